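---
title: "Saddle-point search with exact and quasi-Newton Hessians: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saddle-point search with exact and quasi-Newton Hessians}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hesstate)
```

# The problem

A transition state is a first-order saddle point of the potential-energy
surface: a stationary point whose Hessian has exactly one negative
eigenvalue. Locating one requires second-order information — the update
direction must *maximize* the energy along one Hessian eigenmode while
minimizing along all others — and in routine practice that information is
approximated from gradients by quasi-Newton (QN) updates, because exact
second derivatives of ab initio energies are expensive. When a surface is
cheap to differentiate twice (an analytic form, or a smooth learned
surrogate), the exact Hessian can instead be recomputed at *every* step.
This package implements both regimes with an otherwise identical
optimizer, so their efficiency and robustness can be compared cleanly, and
supplies analytic reactive toy surfaces on which every quantity has an
exact, independently computed reference.

# The optimizer

## RS-PRFO stepping

At each step the (projected) Hessian is diagonalized; the *leftmost* mode
is the followed mode. Its displacement uses the higher root of the 2×2
augmented eigenproblem `[[h1, g1], [g1, 0]]` (energy maximization); the
remaining modes use the lowest root of their jointly augmented problem
(energy minimization). Each per-mode displacement is
`-g_i / (h_i - lambda_partition)`.

When the unrestricted step exceeds the trust radius, the two partition
shifts are moved apart by a common restriction parameter `t >= 0`
(`lambda_max + t`, `lambda_min - t`), which shrinks every mode
displacement monotonically; `t` is found by bisection until the step norm
equals the radius to 1e-10. This is a Levenberg-style restricted-step
shift rather than a crude truncation: the step direction rotates toward
the safest descent/ascent combination as the radius tightens.

Numerical details:

* **Degenerate denominators.** If `h_i - lambda` falls below 1e-14 it is
  replaced by ±1e-14 (sign preserved), which only occurs for exactly
  degenerate augmented roots.
* **Zero modes.** Eigenvalues below `1e-8 × max(|h|)` with negligible
  gradient components (projected translations/rotations) are excluded
  from the partitions.
* **Followed-mode ties.** Exact leftmost degeneracy is broken by
  eigenvector sign-fixing and ascending-eigenvalue order, which is
  deterministic.

## Trust-radius control

The radius starts at 0.1 Å and is adapted from the *improper ratio*
`max(|predicted/actual|, |actual/predicted|) >= 1` between the quadratic
model's predicted energy change and the observed one: below 1.035 the
radius grows by 1.15; above 5.0 it shrinks by 0.65. Two cases the ratio
does not define are resolved as: sign disagreement between predicted and
actual change → worst case (shrink); both changes exactly zero → perfect
agreement (grow). The radius is clamped to `[1e-5, 0.3]` Å (tool
defaults). A period-2 limit cycle — two alternating positions with
consistent mid-range ratios, which the controller cannot detect — forces
an additional shrink.

## Exact-Hessian mode extras

Because the exact Hessian is available at every step, the optimizer knows
the index of any gradient-converged point. If that index is not 1, it
escapes along the spurious mode (the second negative mode at an
index-≥2 point, the softest nonzero mode at a minimum) with a
trust-radius-sized displacement, up to 10 times, instead of reporting a
wrong-index "success". This is standard eigenvector-following practice
and is exactly the information a QN Hessian cannot provide.

## Quasi-Newton mode

The initial Hessian is a curvature-scaled identity whose leftmost
direction is refined by Davidson iteration (below); the scale defaults to
the magnitude of the Davidson eigenvalue. Updates use a symmetric secant
formula that is *not* forced positive definite — BFGS proper cannot
represent the indefinite Hessians a saddle search needs. The formula is
Bofill's hybrid: with residual `r = y - H s`,

```
H' = H + phi * (r r') / (r's)            (SR1 part)
       + (1 - phi) * [ (r s' + s r')/s's - (r's) s s' / (s's)^2 ]  (PSB part)
phi = (r's)^2 / (|r|^2 |s|^2)
```

which satisfies `H's = y` exactly, stays symmetric, and degrades
gracefully to PSB when the SR1 denominator vanishes. If the improper
ratio exceeds its upper threshold for 3 consecutive steps, the QN Hessian
is rebuilt from scratch (Davidson-refined identity); the rebuild's
gradient calls are charged to the *inclusive* accounting.

## Gradient-call accounting

Two bases are recorded: *exclusive* counts one gradient evaluation per
optimization step; *inclusive* adds the finite-difference gradient calls
spent constructing or reconstructing QN Hessians (Davidson products).
Exact-Hessian runs have identical counts on both bases; QN runs do not,
so the inclusive comparison widens the gap between the two modes.

## Davidson / Olsen leftmost eigenpair

Hessian-vector products are central finite differences of the gradient
(step 1e-4 Å, 2 calls per product). The subspace grows Rayleigh–Ritz
style from residuals orthogonalized against the current basis (an Olsen
correction with identity preconditioner — the Hessian diagonal is not
available without building the matrix). Iteration stops at relative
residual 0.1 by default (configurable; the unit tests use 1e-3 where
eigenvector accuracy is asserted).

# The surfaces

Three analytic surfaces provide exact energies, gradients and Hessians;
units are an arbitrary consistent energy unit with lengths in Å and
masses in amu.

* **`mueller_brown_2d`** — the standard four-Gaussian two-dimensional
  test surface (3 minima, 2 saddles), embedded as a single pseudo-atom
  `X` (mass 1) in 3D with a stiff harmonic tether `kz/2 z²` (kz = 100)
  so all code paths are uniformly 3N-dimensional; the tether adds one
  positive eigenvalue and changes nothing else. Derivatives are closed
  form.
* **`morse_exchange_abc`** — an F–H–O triatomic bond-exchange surface:
  Morse wells (D = 100, a = 1.5, r0 = 0.96 Å) on F–H and H–O, an
  anti-bonding bond-order coupling `c_rep n_FH n_HO` with
  `n = exp(-a(r - r0))` and `c_rep = 250 > 2D`, which destabilizes
  simultaneous bonding and makes the symmetric configuration an index-1
  saddle, and a shallow Morse-type van der Waals well (Dv = 3, av = 1,
  rv = 2.8 Å) on F–O that keeps the dissociated fragments at finite
  separation. The surface has two degenerate deep wells whose bonding
  graphs differ (F–H + O vs F + H–O), two shallow linear saddles, and
  the bond-exchange saddle (the highest). Elements F/H/O give the
  endpoint graphs distinct labels, so the exchange reaction is
  *chemical* by the graph test. Derivatives are closed form through the
  pairwise-distance chain rule.
* **`torsion_tetramer`** — a C₄ chain with stiff harmonic bonds
  (kb = 300, r0 = 1.5 Å), harmonic bending in cos θ (ka = 50,
  θ0 ≈ 109.47°) and a torsional double well written in the polynomial
  dihedral form `v_bar (n1·n2)²/(|b1|²|b2|⁴|b3|²)` (v_bar = 5), i.e.
  `cos²φ sin²θ1 sin²θ2`. The polynomial form matters: the normalized
  `cos φ` is 0/0 at collinear bond angles and would break the C²
  guarantee exactly where a distorted optimization run can wander. The
  two minima (φ = ±90°) are mirror-image conformers with identical
  graphs, so its saddles are *conformational*. Second derivatives are
  propagated by an internal second-order forward-mode (hyper-dual)
  arithmetic — exact to machine precision, not finite differences.

The **oracle** (`find_stationary_oracle`) locates stationary points by
dense seeded multi-start Newton polish with the analytic Hessian,
classifying each converged point by the inertia of the projected Hessian.
It shares no code with the RS-PRFO optimizer and is the reference for
every derived expectation in the test suite.

# The learned surrogate

The surrogate exists to demonstrate the central mechanism: a model
trained only on energies and forces, smooth enough to differentiate
twice, yields usable Hessians with no Hessian training data.

* **Features.** Per atom, 20 Gaussian radial basis functions (centres
  uniform on [0, 5] Å, width set by the centre spacing) times a quintic
  polynomial cutoff whose value and first two derivatives vanish at
  5 Å, summed over neighbours in separate channels per neighbour
  element. Features depend on interatomic distances only, so the
  predicted energy is exactly invariant to permutation (within an
  element), translation and rotation.
* **Network.** One shared SiLU hidden layer (width 48 by default) maps
  normalized features to per-atom energies; the molecular energy is
  their sum plus per-element biases (initialized by least squares — toy
  atoms have no tabulated reference energies) and a constant output
  scale set from the residual-energy spread. SiLU and the quintic
  cutoff keep the model C², which is the entire requirement for
  well-defined analytic Hessians.
* **Derivatives.** The gradient and Hessian are exact chain-rule
  derivatives of the model (network input-Hessian plus feature curvature
  terms) — equivalent to what reverse-mode automatic differentiation
  would produce. A model configured with a non-C² activation (`relu` is
  included for exactly this purpose) is refused by `hessian_autodiff`
  with an explicit smoothness error.
* **Loss.** Weighted mean-squared error with the energy term per
  configuration and the force term per 3A force components, weights
  λ_E = 1 and λ_F = 20, plus L2 of 1e-5 on all parameters. Minimized by
  mini-batch Adam, batch 100, initial learning rate 1e-4, decayed by
  0.7 on validation plateau. The plateau patience is 150 epochs (no
  improvement > 1e-4 relative): with a few hundred records the epoch
  contains only ~6 mini-batch steps, so a short patience would decay
  the rate to zero long before convergence — the patience is a
  schedule choice of this package, scaled to its data volume.
* **Ensemble.** `ensemble_predict_with_dixon` implements consensus over
  four independently seeded members with at most one member removed by
  Dixon's Q test at the 95% level (Q = gap to nearest neighbour over
  range, critical value 0.829 for n = 4 from the standard table; a zero
  range retains all members).

# The synthetic training distribution

`sample_training_set` emulates a reaction-path training corpus:
configurations are Gaussian displacements (default σ = 0.05 Å) around
points interpolated along each minimum–saddle–minimum path, with 60% of
path samples drawn from the middle third (the transition-state region) —
a deliberately TS-enriched distribution — plus an optional augmentation
in which one bonded pair is compressed to 72–95% of its equilibrium
length. Labels are the exact analytic energies and forces of the
generating surface (noise only if explicitly configured).

Two robustness details: path anchors are Kabsch-aligned onto the saddle
frame before interpolation (unaligned interpolation sweeps through atom
collisions), and draws are rejected and retried when any pair distance
falls below 0.45 Å or the energy exceeds the highest saddle by ten times
the stationary-energy range — linear interpolation between aligned
anchors can still cut corners through unphysical configurations. The
path skeleton always comes from the oracle's default seed: stationary
points are properties of the surface, not of the sampling draw, so two
sets sampled with different seeds share one skeleton.

What the generator does *not* emulate: conformational diversity across
thousands of distinct molecules, DFT-level label noise, multireference
regions, or any chemistry beyond the three toys. Passing tests therefore
demonstrate the *mechanism* — second derivatives of a force-trained C²
model are accurate near the sampled paths — not chemical accuracy on
real systems.

# Reaction-path analysis and outcome classification

The IRC is followed by damped steepest descent in mass-weighted
coordinates with per-step displacement capped at 0.1 Å·amu^1/2, seeded
±0.01 Å·amu^1/2 along the imaginary mode. Steps that would raise the
energy are halved and retried, so recorded energies are monotonically
non-increasing; descent hands over to a trust-region BFGS minimizer
(positive-definite safeguarded) when the gradient tolerance, the
1000-step cap, or an energy decrease below 1e-10 per step is reached.
The gradient tolerance (1e-6, toy units) is shared with the saddle
optimizer.

Connectivity graphs bond two atoms within 1.2× the sum of their Cordero
covalent radii (the scale is a tool default, exposed as a parameter);
graphs are compared by element-label-preserving VF2 isomorphism. An
outcome is `two_end` when the unordered pair of IRC endpoint graphs
matches the intended reactant/product graphs, `one_end` when exactly one
endpoint matches either, `none` otherwise — endpoints are treated as an
unordered pair because branch direction is arbitrary. A saddle is
*conformational* iff its two endpoint graphs are isomorphic to each
other. Optimization path lengths sum Kabsch-aligned (proper rotations
only) Cartesian distances over consecutive trajectory frames and are
reported only for two_end outcomes.

# The benchmark protocol

The frozen suite holds one reaction per surface (reference saddle plus
intended endpoints defined by the exact-potential IRC). Each run
perturbs the saddle with a 5 pm baseline Gaussian displacement — the
guess is meant to be an *approximation* of the TS, as template-generated
guesses are — plus the robustness-grid noise (0–50 pm), optimizes with
one Hessian source, follows the IRC and classifies the outcome. The
same guess is shared by both modes (paired comparison); "success" means
converged to an index-1 saddle *and* a two_end match. Replicates: 5
seeds × 3 surfaces per (noise, mode) cell. Aggregates are a pure
function of the per-run records and are recomputed in the tests.

Problem sizes throughout the suite were chosen so the full test run and
the acceptance script each complete in minutes on one core: 600 + 100
training records, 150 held-out records, 20 recovery guesses per surface,
150 benchmark runs.

A desk-scale caveat the package reports honestly: on systems this small,
50 pm per-coordinate noise is a proportionally enormous distortion (for
the 2D surface it displaces the entire "molecule" by ~0.7 Å against
well separations of order 1 Å), and single paired runs exist where the
exact-Hessian search honestly converges to a different genuine saddle —
or orbits a saddle-free convex region — while the quasi-Newton run
succeeds by the luck of its stale Hessian. The robustness comparison at
this scale is therefore directional, not a guarantee per noise level.

# Known limitations

* Cartesian coordinates only (with optional translation/rotation
  projection); no redundant internal coordinates or geodesic stepping,
  so step quality on strongly curved valleys is poorer than
  internal-coordinate optimizers achieve.
* The surrogate's radial features cannot distinguish neighbours of the
  same element at equal distances in different directions (no angular
  information); this is sufficient for the toys, not for general
  chemistry.
* The IRC integrator is damped steepest descent, not a higher-order
  path integrator; path geometry between endpoints is approximate even
  though the endpoints are polished to tight tolerance.
* Hessian serialization is plain text and JSON only.

# A worked example

```{r example, eval = FALSE}
pot <- toy_potential("morse_exchange_abc")
sad <- find_stationary_oracle(pot, "saddle")[[3]]   # the exchange saddle
fit <- optimize_saddle(pot, perturb_guess(sad, sigma_pm = 5, seed = 2))
summary(fit)

irc <- follow_irc(pot, fit)
classify_outcome(irc, find_stationary_oracle(pot, "minimum")[[1]],
                 find_stationary_oracle(pot, "minimum")[[2]])
```
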