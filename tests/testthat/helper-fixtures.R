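# Shared fixtures: cached oracle lookups and small builders used across
# test files.  The package memoizes oracle searches per session, so these
# are cheap after first use.

all_surfaces <- c("mueller_brown_2d", "morse_exchange_abc",
                  "torsion_tetramer")

oracle_minima <- function(name) {
  find_stationary_oracle(toy_potential(name), "minimum", seed = 1L)
}

oracle_saddles <- function(name) {
  find_stationary_oracle(toy_potential(name), "saddle", seed = 1L)
}

# the bond-exchange saddle of the triatomic surface (its highest saddle)
exchange_saddle <- function() {
  s <- oracle_saddles("morse_exchange_abc")
  s[[length(s)]]
}

# geometry distance measure appropriate to the surface: plain Euclidean for
# the fixed-frame 2D surface, Kabsch RMSD for invariant molecular toys
geom_dist <- function(name, a, b) {
  if (name == "mueller_brown_2d")
    sqrt(sum((coords_vector(a) - coords_vector(b))^2))
  else kabsch_rmsd(a$coords, b$coords)
}

# random valid geometry near the reactive region of a surface
random_geometry <- function(name, seed) {
  set.seed(seed)
  pot <- toy_potential(name)
  base <- if (name == "mueller_brown_2d") {
    ms <- oracle_minima(name)
    ms[[sample.int(length(ms), 1)]]
  } else {
    pts <- c(oracle_minima(name), oracle_saddles(name))
    pts[[sample.int(length(pts), 1)]]
  }
  set_coords(base, coords_vector(base) +
               rnorm(3 * n_atoms(base), sd = 0.06))
}

# one small trained surrogate shared by the whole test session
trained_surrogate <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pot <- toy_potential("morse_exchange_abc")
      ds <- sample_training_set(pot, n_path = 600, n_compressed = 100,
                                seed = 11)
      cache <<- train_surrogate(ds, training_config(seed = 1))
    }
    cache
  }
})

fd_gradient <- function(potential, geom, h = 1e-5) {
  x0 <- coords_vector(geom)
  vapply(seq_along(x0), function(k) {
    xp <- x0; xp[k] <- xp[k] + h
    xm <- x0; xm[k] <- xm[k] - h
    (pes_eval(potential, set_coords(geom, xp))$energy -
       pes_eval(potential, set_coords(geom, xm))$energy) / (2 * h)
  }, 0)
}

fd_hessian_of <- function(potential, geom, h = 1e-4) {
  finite_difference_hessian(function(g) pes_eval(potential, g)$gradient,
                            geom, step = h)$matrix
}
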