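# Brute-force stationary-point oracle: dense multi-start Newton polish with
# the analytic Hessian, independent of the RS-PRFO optimizer.  Used to
# locate reference minima/saddles and as the source of all derived expected
# values in the tests.

.oracle_cache <- new.env(parent = emptyenv())

# Newton polish to a stationary point of any index.  Steps are taken in the
# translation/rotation-free subspace for invariant (multi-atom) potentials.
.newton_polish <- function(potential, geom, project, gtol = 1e-11,
                           max_iter = 120L, max_step = 0.25) {
  x <- coords_vector(geom)
  for (it in seq_len(max_iter)) {
    g0 <- set_coords(geom, x)
    ev <- tryCatch(pes_eval(potential, g0, hessian = TRUE),
                   error = function(e) NULL)
    if (is.null(ev) || !all(is.finite(ev$gradient))) return(NULL)
    g <- ev$gradient; H <- ev$hessian
    if (project) {
      P <- tr_projector(g0)
      g <- as.numeric(P %*% g)
      H <- P %*% H %*% P
    }
    if (max(abs(g)) <= gtol)
      return(list(geometry = g0, eval = ev, max_grad = max(abs(g))))
    eg <- eigen((H + t(H)) / 2, symmetric = TRUE)
    keep <- abs(eg$values) > 1e-7 * max(abs(eg$values), 1)
    if (!any(keep)) return(NULL)
    gq <- crossprod(eg$vectors[, keep, drop = FALSE], g)
    step <- -as.numeric(eg$vectors[, keep, drop = FALSE] %*%
                          (gq / eg$values[keep]))
    ns <- sqrt(sum(step^2))
    if (ns > max_step) step <- step * (max_step / ns)
    x <- x + step
    if (!all(is.finite(x))) return(NULL)
  }
  NULL
}

# seeded start geometries for the multi-start search
.oracle_starts <- function(potential, seed, region = NULL) {
  set.seed(seed)
  ref <- reference_geometry(potential)
  switch(potential$name,
    mueller_brown_2d = {
      lo <- if (is.null(region)) c(-1.7, -0.5) else region$lower
      hi <- if (is.null(region)) c(1.3, 2.3) else region$upper
      gx <- seq(lo[1], hi[1], length.out = 20)
      gy <- seq(lo[2], hi[2], length.out = 20)
      pts <- expand.grid(x = gx, y = gy)
      lapply(seq_len(nrow(pts)), function(i)
        set_coords(ref, c(pts$x[i], pts$y[i], 0)))
    },
    morse_exchange_abc = {
      # F at origin, H on the x axis, O at distance r2 from H at polar
      # angle beta (beta ~ pi places O on the far side of F)
      pts <- expand.grid(r1 = c(0.9, 0.96, 1.3, 1.8, 2.6),
                         r2 = c(0.85, 0.96, 1.2, 1.5, 2.0, 2.8,
                                3.6, 4.5, 6.0, 7.5, 9.0),
                         beta = c(0, pi / 4, pi / 2, 3 * pi / 4, 0.97 * pi))
      lapply(seq_len(nrow(pts)), function(i) {
        set_coords(ref, c(0, 0, 0,
                          pts$r1[i], 0, 0,
                          pts$r1[i] + pts$r2[i] * cos(pts$beta[i]),
                          pts$r2[i] * sin(pts$beta[i]),
                          stats::rnorm(1, sd = 0.01)))
      })
    },
    torsion_tetramer = {
      p <- potential$params
      th <- acos(p$cos_theta0)
      phis <- seq(-pi, pi, length.out = 25)
      lapply(phis, function(phi) {
        p1 <- c(0, 0, 0); p2 <- c(p$r0, 0, 0)
        p3 <- p2 + p$r0 * c(cos(pi - th), sin(pi - th), 0)
        p4 <- .place_fourth(p1, p2, p3, p$r0, th, phi)
        X <- rbind(p1, p2, p3, p4) +
          matrix(stats::rnorm(12, sd = 0.02), 4, 3)
        set_coords(ref, as.numeric(t(X)))
      })
    })
}

.in_region <- function(geom, region) {
  if (is.null(region)) return(TRUE)
  xy <- geom$coords[1, 1:2]
  all(xy >= region$lower - 1e-9) && all(xy <= region$upper + 1e-9)
}

#' Locate stationary points by exhaustive multi-start Newton search
#'
#' An independent oracle: dense seeded multi-start Newton polish using the
#' analytic Hessian, classifying each converged point by the inertia of the
#' (translation/rotation-projected) Hessian.  It shares no code with the
#' RS-PRFO optimizer and is the reference for every derived expected value.
#'
#' @param potential a \code{toy_potential}.
#' @param kind \code{"minimum"} (Hessian index 0) or \code{"saddle"}
#'   (index 1).
#' @param region optional search bounds, a list with \code{lower} and
#'   \code{upper} length-2 vectors (x, y; used by the 2D surface).
#' @param seed integer seed; results are bit-for-bit reproducible per seed.
#' @return list of \code{geometry} objects, each with
#'   \code{attr(, "eigenvalues")} (projected Hessian spectrum) and
#'   \code{attr(, "energy")}; ordered by energy.  Empty list with a warning
#'   if no stationary point of the requested index lies in the region.
#' @export
find_stationary_oracle <- function(potential, kind = c("minimum", "saddle"),
                                   region = NULL, seed = 1L) {
  kind <- match.arg(kind)
  all_pts <- .oracle_all(potential, region, seed)
  target_index <- if (kind == "minimum") 0L else 1L
  out <- Filter(function(g) attr(g, "index") == target_index, all_pts)
  if (!length(out))
    warning("no stationary point of kind '", kind,
            "' found in the search region for ", potential$name)
  out
}

# one cached multi-start search per (potential, region, seed); stationary
# points of every index are collected and classified, then filtered by kind
.oracle_all <- function(potential, region, seed) {
  key <- paste(potential$name,
               paste(unlist(potential$params), collapse = ","),
               seed, paste(unlist(region), collapse = ","), sep = "|")
  if (!is.null(.oracle_cache[[key]])) return(.oracle_cache[[key]])
  project <- potential$name != "mueller_brown_2d"
  starts <- .oracle_starts(potential, seed, region)
  found <- list()
  for (s in starts) {
    res <- .newton_polish(potential, s, project)
    if (is.null(res)) next
    if (!.in_region(res$geometry, region)) next
    # reject run-away dissociated geometries (pairs far beyond interaction)
    if (n_atoms(res$geometry) > 1 &&
        max(stats::dist(res$geometry$coords)) > 12) next
    dup <- FALSE
    for (f in found) {
      same <- if (project)
        kabsch_rmsd(res$geometry$coords, f$coords) < 1e-4
      else
        sqrt(sum((coords_vector(res$geometry) - coords_vector(f))^2)) < 1e-4
      if (same) { dup <- TRUE; break }
    }
    if (dup) next
    H <- res$eval$hessian
    if (project) {
      P <- tr_projector(res$geometry)
      H <- P %*% H %*% P
    }
    md <- normal_modes(hessian_matrix(H, projected = project),
                       zero_tol = 1e-6)
    g <- res$geometry
    attr(g, "eigenvalues") <- md$eigenvalues
    attr(g, "energy") <- res$eval$energy
    attr(g, "index") <- md$n_negative
    found[[length(found) + 1L]] <- g
  }
  found <- found[order(vapply(found, function(g) attr(g, "energy"), 0))]
  .oracle_cache[[key]] <- found
  found
}
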