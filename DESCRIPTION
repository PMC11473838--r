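Package: hesstate
Title: Transition-State Optimization with Exact Analytic Hessians on Toy Reactive Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating first-order saddle points (transition states)
    on smooth potential-energy surfaces using restricted-step partitioned
    rational function optimization (RS-PRFO) driven either by exact analytic
    Hessians or by TS-BFGS quasi-Newton updates. Provides analytic toy
    reactive surfaces (Mueller-Brown, a triatomic bond-exchange surface, a
    torsional tetramer) with closed-form gradients and Hessians, a minimal
    twice-differentiable learned surrogate potential trained on energies and
    forces whose Hessians are obtained by exact analytic differentiation,
    Davidson/Olsen iterative leftmost-eigenpair refinement from gradient
    calls, trust-radius control, intrinsic reaction coordinate following,
    molecular-graph outcome classification, Kabsch-aligned path lengths, and
    a full-versus-quasi-Newton benchmark harness with a Gaussian-noise
    robustness protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
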