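#' Configuration set of (geometry, energy, forces) records
#'
#' The training container for the surrogate potential.  Forces are stored
#' with the convention force = -gradient and, unless a noise level was
#' explicitly configured at sampling time, are the exact analytic forces of
#' the generating potential.
#'
#' @param records list of lists with fields \code{geometry}, \code{energy},
#'   \code{forces} (length-3N numeric).
#' @param provenance list describing the sampling recipe (potential name,
#'   counts, scale, seed).
#' @return object of class \code{"configuration_set"}.
#' @export
configuration_set <- function(records, provenance = list()) {
  for (r in records) {
    stopifnot(inherits(r$geometry, "geometry"),
              length(r$forces) == 3L * n_atoms(r$geometry),
              is.finite(r$energy))
  }
  structure(list(records = records, provenance = provenance),
            class = "configuration_set")
}

#' @export
print.configuration_set <- function(x, ...) {
  cat("<configuration_set>", length(x$records), "records")
  if (length(x$provenance))
    cat(" (", paste(names(x$provenance), unlist(lapply(x$provenance, paste,
        collapse = "/")), sep = "=", collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.configuration_set <- function(x) length(x$records)

# bonded pairs and their equilibrium lengths for the compression move
.equilibrium_bonds <- function(potential) {
  p <- potential$params
  switch(potential$name,
    morse_exchange_abc = list(pairs = rbind(c(1L, 2L), c(2L, 3L)),
                              r0 = c(p$r0, p$r0)),
    torsion_tetramer = list(pairs = rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L)),
                            r0 = rep(p$r0, 3)),
    stop("potential ", potential$name, " has no bonded pairs to compress"))
}

#' Sample a synthetic training set from a toy surface
#'
#' Emulates a reaction-path training distribution: configurations are
#' Gaussian displacements around points interpolated along the piecewise
#' linear minimum-saddle-minimum path(s) of the surface, with 60% of the
#' path samples drawn from the middle third of each path (the
#' transition-state region) and 40% spread uniformly, plus an optional
#' bond-compression augmentation in which one randomly chosen bonded pair is
#' shrunk below its equilibrium length.  Every record carries the exact
#' analytic energy and forces of the generating potential (no noise unless
#' \code{noise_sd > 0} is explicitly configured).
#'
#' @param potential a \code{toy_potential}.
#' @param n_path number of path-region samples.
#' @param n_compressed number of compressed-bond samples.
#' @param temperature_like_scale standard deviation (Angstrom) of the
#'   isotropic Gaussian displacement applied to every sampled point
#'   (default 0.05).
#' @param seed integer seed; sampling is deterministic per seed.
#' @param noise_sd optional Gaussian noise added to stored energies/forces
#'   (default 0: stored labels are exact).
#' @return a \code{configuration_set}.
#' @export
sample_training_set <- function(potential, n_path, n_compressed = 0L,
                                temperature_like_scale = 0.05, seed = 1L,
                                noise_sd = 0) {
  if (n_path < 0 || n_compressed < 0) stop("counts must be non-negative")
  set.seed(seed)
  records <- list()
  if (n_path + n_compressed == 0L)
    return(configuration_set(list(), provenance = list(
      potential = potential$name, n_path = 0L, n_compressed = 0L,
      seed = seed)))

  # stationary points are properties of the surface, not of the sampling
  # draw: locate them with the oracle's fixed default seed so every sampled
  # set shares one path skeleton
  minima <- find_stationary_oracle(potential, "minimum", seed = 1L)
  saddles <- find_stationary_oracle(potential, "saddle", seed = 1L)
  set.seed(seed)
  if (!length(minima) || !length(saddles))
    stop("no path endpoints available for ", potential$name)

  # piecewise linear min -> saddle -> min paths (each saddle joined to its
  # two nearest distinct minima); anchors are Kabsch-aligned onto the saddle
  # frame so interpolation does not sweep through spurious rigid motion
  paths <- lapply(saddles, function(s) {
    d <- vapply(minima, function(m)
      kabsch_rmsd(s$coords, m$coords, weights = s$masses), 0)
    ord <- order(d)
    a <- minima[[ord[1]]]
    b <- minima[[ord[min(2, length(ord))]]]
    align <- function(m) {
      if (n_atoms(s) < 2) return(coords_vector(m))
      as.numeric(t(kabsch_align(m$coords, s$coords,
                                weights = s$masses)$coords))
    }
    list(a = align(a), s = coords_vector(s), b = align(b))
  })
  # acceptance window: reject unphysical near-collisions and energies far
  # above the highest saddle (linear interpolation can cut corners)
  e_cap <- max(vapply(saddles, function(s) attr(s, "energy"), 0)) +
    10 * abs(diff(range(c(
      vapply(minima, function(m) attr(m, "energy"), 0),
      vapply(saddles, function(s) attr(s, "energy"), 0)))))
  acceptable <- function(g, e) {
    (n_atoms(g) < 2 || min(stats::dist(g$coords)) > 0.45) && e <= e_cap
  }

  path_point <- function(path, t) {
    # t in [0, 1]; 0.5 is the saddle
    if (t <= 0.5) path$a + (path$s - path$a) * (t / 0.5)
    else path$s + (path$b - path$s) * ((t - 0.5) / 0.5)
  }

  ref <- reference_geometry(potential)
  mk_record <- function(x) {
    g <- set_coords(ref, x)
    ev <- pes_eval(potential, g)
    e <- ev$energy
    f <- -ev$gradient
    if (noise_sd > 0) {
      e <- e + stats::rnorm(1, sd = noise_sd)
      f <- f + stats::rnorm(length(f), sd = noise_sd)
    }
    list(geometry = g, energy = e, forces = f)
  }

  n <- length(coords_vector(ref))
  draw_accepted <- function(gen) {
    for (try in 1:60) {
      rec <- mk_record(gen())
      if (acceptable(rec$geometry, rec$energy)) return(rec)
    }
    stop("could not draw an acceptable configuration in 60 tries")
  }
  for (i in seq_len(n_path)) {
    path <- paths[[1L + (i - 1L) %% length(paths)]]
    records[[length(records) + 1L]] <- draw_accepted(function() {
      t <- if (stats::runif(1) < 0.6) stats::runif(1, 1 / 3, 2 / 3)
           else stats::runif(1)
      path_point(path, t) + stats::rnorm(n, sd = temperature_like_scale)
    })
  }

  if (n_compressed > 0L) {
    bonds <- .equilibrium_bonds(potential)
    for (i in seq_len(n_compressed)) {
      path <- paths[[1L + (i - 1L) %% length(paths)]]
      records[[length(records) + 1L]] <- draw_accepted(function() {
        x <- path_point(path, stats::runif(1)) +
          stats::rnorm(n, sd = temperature_like_scale / 2)
        k <- sample(nrow(bonds$pairs), 1L)
        i1 <- bonds$pairs[k, 1]; i2 <- bonds$pairs[k, 2]
        X <- matrix(x, ncol = 3, byrow = TRUE)
        dvec <- X[i2, ] - X[i1, ]
        r <- sqrt(sum(dvec^2))
        target <- stats::runif(1, 0.72, 0.95) * bonds$r0[k]
        X[i2, ] <- X[i1, ] + dvec * (target / r)
        as.numeric(t(X))
      })
    }
  }

  configuration_set(records, provenance = list(
    potential = potential$name, n_path = as.integer(n_path),
    n_compressed = as.integer(n_compressed),
    temperature_like_scale = temperature_like_scale, seed = seed,
    noise_sd = noise_sd))
}

#' Perturb a geometry with Gaussian coordinate noise
#'
#' Adds i.i.d. zero-mean Gaussian displacement to every Cartesian component,
#' the protocol used to degrade initial saddle guesses in the robustness
#' benchmark.
#'
#' @param geometry a \code{geometry}.
#' @param sigma_pm noise standard deviation in picometres (50 pm = 0.5
#'   Angstrom); non-negative.
#' @param seed integer seed; deterministic per seed.
#' @return a perturbed \code{geometry}.
#' @export
perturb_guess <- function(geometry, sigma_pm, seed = 1L) {
  if (sigma_pm < 0) stop("sigma_pm must be non-negative")
  set.seed(seed)
  x <- coords_vector(geometry)
  set_coords(geometry, x + stats::rnorm(length(x), sd = sigma_pm / 100))
}
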