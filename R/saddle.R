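#' Trust-radius state for RS-PRFO optimization
#'
#' Holds the current trust radius and the controller constants: the radius
#' starts at 0.1 Angstrom and, based on the improper ratio (>= 1) between
#' predicted and actual energy change of each accepted step, grows by a
#' factor 1.15 when the ratio is below 1.035 and shrinks by 0.65 when the
#' ratio is above 5.0.
#'
#' @param radius initial trust radius (Angstrom), default 0.1.
#' @param ratio_low grow threshold on the improper ratio (1.035).
#' @param ratio_high shrink threshold (5.0).
#' @param grow growth factor (1.15).
#' @param shrink shrink factor (0.65).
#' @param radius_min,radius_max clamps on the radius.
#' @return object of class \code{"trust_state"}.
#' @export
trust_state <- function(radius = 0.1, ratio_low = 1.035, ratio_high = 5.0,
                        grow = 1.15, shrink = 0.65,
                        radius_min = 1e-5, radius_max = 0.3) {
  stopifnot(radius > 0, radius_min <= radius, radius <= radius_max)
  structure(list(radius = radius, ratio_low = ratio_low,
                 ratio_high = ratio_high, grow = grow, shrink = shrink,
                 radius_min = radius_min, radius_max = radius_max),
            class = "trust_state")
}

#' Update the trust radius from predicted vs actual energy change
#'
#' The step-quality signal is the improper ratio
#' \code{max(|predicted/actual|, |actual/predicted|)} (>= 1).  A sign
#' disagreement between predicted and actual change is treated as the worst
#' case (infinite ratio, forcing a shrink); both changes exactly zero count
#' as perfect agreement (ratio 1, grow).  The radius is clamped to
#' \code{[radius_min, radius_max]}.
#'
#' @param trust a \code{trust_state}.
#' @param predicted_de quadratic-model energy change of the accepted step.
#' @param actual_de observed energy change.
#' @return the updated \code{trust_state}, with the ratio used stored in
#'   \code{attr(, "ratio")}.
#' @export
update_trust_radius <- function(trust, predicted_de, actual_de) {
  if (predicted_de == 0 && actual_de == 0) {
    ratio <- 1
  } else if (predicted_de == 0 || actual_de == 0 ||
             sign(predicted_de) != sign(actual_de)) {
    ratio <- Inf
  } else {
    ratio <- max(abs(predicted_de / actual_de),
                 abs(actual_de / predicted_de))
  }
  r <- trust$radius
  if (ratio < trust$ratio_low) r <- r * trust$grow
  else if (ratio > trust$ratio_high) r <- r * trust$shrink
  trust$radius <- min(max(r, trust$radius_min), trust$radius_max)
  attr(trust, "ratio") <- ratio
  trust
}

#' Restricted-step partitioned rational function optimization step
#'
#' Partitions the eigenspace into the followed mode (energy maximized) and
#' its complement (energy minimized).  The followed mode's displacement uses
#' the higher root of its 2 x 2 augmented eigenproblem, the complement the
#' lowest root of its augmented problem; each per-mode displacement is
#' \code{-g_i / (h_i - lambda_partition)}.  When the unrestricted step
#' exceeds the trust radius, both partition shifts are moved apart by a
#' common restriction parameter found by bisection (to 1e-10) so that the
#' step norm equals the radius exactly, rather than truncating the step.
#'
#' @param gradient gradient in Cartesian coordinates (length matches modes).
#' @param modes a \code{mode_set} from the current Hessian (zero
#'   translation/rotation modes of a projected Hessian are ignored
#'   automatically).
#' @param trust a \code{trust_state} (or a numeric radius).
#' @param followed_mode index into the non-zero modes of the mode to
#'   maximize along; default 1 (leftmost).
#' @return the step vector; \code{attr(, "predicted_de")} holds the
#'   quadratic-model energy change.
#' @export
prfo_step <- function(gradient, modes, trust, followed_mode = 1L) {
  radius <- if (inherits(trust, "trust_state")) trust$radius else trust
  vals <- modes$eigenvalues; vecs <- modes$eigenvectors
  scale <- max(abs(vals), 1)
  live <- abs(vals) > 1e-8 * scale
  # keep modes with meaningful gradient even if tiny curvature
  gq_all <- as.numeric(crossprod(vecs, gradient))
  live <- live | abs(gq_all) > 1e-10 * max(1, max(abs(gq_all)))
  h <- vals[live]; V <- vecs[, live, drop = FALSE]
  gq <- gq_all[live]
  if (!length(h) || sqrt(sum(gq^2)) == 0) {
    step <- numeric(length(gradient))
    attr(step, "predicted_de") <- 0
    return(step)
  }
  f <- followed_mode
  if (f < 1L || f > length(h)) stop("followed_mode out of range")
  idx_max <- f
  idx_min <- setdiff(seq_along(h), f)

  step_q <- function(t) {
    # t >= 0 moves the two partition shifts apart (Levenberg-style
    # restriction); t = 0 is the unrestricted P-RFO step
    q <- numeric(length(h))
    hm <- h[idx_max]; gm <- gq[idx_max]
    lam_max <- (hm + sqrt(hm^2 + 4 * gm^2)) / 2 + t   # higher root, shifted up
    dm <- hm - lam_max
    if (abs(dm) < 1e-14) dm <- -1e-14
    q[idx_max] <- -gm / dm
    if (length(idx_min)) {
      hmin <- h[idx_min]; gmin <- gq[idx_min]
      # lowest eigenvalue of [[diag(h), g], [g', 0]]: root of
      # sum g_i^2/(lam - h_i) = lam below min(h, 0)
      lam_min <- .rfo_lowest_root(hmin, gmin) - t
      dmn <- hmin - lam_min
      dmn[abs(dmn) < 1e-14] <- 1e-14
      q[idx_min] <- -gmin / dmn
    }
    q
  }
  q <- step_q(0)
  if (sqrt(sum(q^2)) > radius) {
    lo <- 0; hi <- 1
    while (sqrt(sum(step_q(hi)^2)) > radius && hi < 1e12) hi <- hi * 4
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (sqrt(sum(step_q(mid)^2)) > radius) lo <- mid else hi <- mid
      if (hi - lo < 1e-10 * max(1, hi)) break
    }
    q <- step_q(hi)
  }
  step <- as.numeric(V %*% q)
  # quadratic model prediction for the accepted step
  attr(step, "predicted_de") <- sum(gq * q) + 0.5 * sum(h * q^2)
  step
}

# lowest eigenvalue of the augmented RFO matrix [[diag(h), g], [g', 0]]
.rfo_lowest_root <- function(h, g) {
  if (!length(h)) return(0)
  nz <- abs(g) > 0
  if (!any(nz)) return(min(0, min(h)) - 0)
  A <- rbind(cbind(diag(h, nrow = length(h)), g), c(g, 0))
  min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
}

#' TS-BFGS quasi-Newton Hessian update
#'
#' Symmetric secant update that is deliberately not forced positive
#' definite, so it can represent the indefinite Hessians needed for saddle
#' searches.  The formula is Bofill's hybrid: a weighted combination of the
#' symmetric rank-one (SR1) and Powell-symmetric-Broyden (PSB) updates with
#' weight \code{phi = ((y - Hs).s)^2 / (|y - Hs|^2 |s|^2)}.  The updated
#' matrix satisfies the secant condition (it maps \code{s} to \code{y}
#' exactly) and remains symmetric.
#'
#' @param H current Hessian approximation (matrix or
#'   \code{hessian_matrix}).
#' @param s displacement vector (step taken).
#' @param y gradient change over the step.
#' @param min_step skip threshold on |s| (update skipped, with a warning).
#' @return updated matrix (plain symmetric matrix).
#' @export
ts_bfgs_update <- function(H, s, y, min_step = 1e-12) {
  if (inherits(H, "hessian_matrix")) H <- H$matrix
  ns2 <- sum(s^2)
  if (sqrt(ns2) < min_step) {
    warning("step norm below threshold; quasi-Newton update skipped")
    return(H)
  }
  r <- y - as.numeric(H %*% s)
  nr2 <- sum(r^2)
  if (nr2 < 1e-30) return(H)                 # y = Hs exactly: no correction
  rs <- sum(r * s)
  phi <- rs^2 / (nr2 * ns2)
  dH_psb <- (tcrossprod(r, s) + tcrossprod(s, r)) / ns2 -
    rs * tcrossprod(s, s) / ns2^2
  if (abs(rs) > 1e-12 * sqrt(nr2 * ns2)) {
    dH_sr1 <- tcrossprod(r, r) / rs
    dH <- phi * dH_sr1 + (1 - phi) * dH_psb
  } else {
    dH <- dH_psb                             # SR1 denominator degenerate
  }
  Hn <- H + dH
  (Hn + t(Hn)) / 2
}

#' Iterative leftmost eigenpair from gradient calls (Davidson/Olsen)
#'
#' Builds the lowest eigenpair of the Hessian without ever forming it:
#' Hessian-vector products are realized as central finite differences of the
#' gradient (2 gradient calls each, step 1e-4 Angstrom), the subspace is
#' grown Rayleigh-Ritz style from the (projected) residuals, and iteration
#' stops when the relative residual |Hv - theta v| / max(|theta|, 1) drops
#' below \code{tol} (default 0.1) or the subspace saturates.
#'
#' @param gradient_fn function(geometry) -> gradient vector.
#' @param geometry the expansion point.
#' @param initial_vector starting direction (default: random, seeded
#'   deterministic); normalized internally.
#' @param fd_step finite-difference step (Angstrom).
#' @param tol relative residual convergence threshold.
#' @param max_iter maximum subspace dimension.
#' @param project project translations/rotations out of the products.
#' @return list with \code{eigenvalue}, \code{eigenvector},
#'   \code{gradient_calls}, \code{converged}, \code{residual}.
#' @export
davidson_leftmost <- function(gradient_fn, geometry, initial_vector = NULL,
                              fd_step = 1e-4, tol = 0.1, max_iter = NULL,
                              project = FALSE) {
  x0 <- coords_vector(geometry)
  n <- length(x0)
  if (is.null(max_iter)) max_iter <- n
  P <- if (project) tr_projector(geometry) else NULL
  g_calls <- 0L
  hvp <- function(v) {
    gp <- gradient_fn(set_coords(geometry, x0 + fd_step * v))
    gm <- gradient_fn(set_coords(geometry, x0 - fd_step * v))
    g_calls <<- g_calls + 2L
    hv <- (gp - gm) / (2 * fd_step)
    if (!is.null(P)) hv <- as.numeric(P %*% hv)
    hv
  }
  if (is.null(initial_vector)) {
    set.seed(20L + n)
    initial_vector <- stats::rnorm(n)
  }
  v <- initial_vector
  if (!is.null(P)) v <- as.numeric(P %*% v)
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("initial vector is zero (after projection)")
  v <- v / nv
  V <- matrix(v, ncol = 1)
  W <- matrix(hvp(v), ncol = 1)
  best <- NULL
  for (it in seq_len(max_iter)) {
    Hs <- crossprod(V, W)
    Hs <- (Hs + t(Hs)) / 2
    eg <- eigen(Hs, symmetric = TRUE)
    k <- which.min(eg$values)
    theta <- eg$values[k]
    u <- as.numeric(V %*% eg$vectors[, k])
    Hu <- as.numeric(W %*% eg$vectors[, k])
    res <- Hu - theta * u
    rn <- sqrt(sum(res^2))
    best <- list(eigenvalue = theta, eigenvector = u / sqrt(sum(u^2)),
                 gradient_calls = g_calls, residual = rn,
                 converged = rn <= tol * max(abs(theta), 1))
    if (best$converged || ncol(V) >= n) break
    # Olsen-style correction with identity preconditioner: expand with the
    # residual orthogonalized against the current subspace
    t_new <- res
    t_new <- t_new - V %*% crossprod(V, t_new)
    tn <- sqrt(sum(t_new^2))
    if (tn < 1e-12) break
    t_new <- as.numeric(t_new) / tn
    V <- cbind(V, t_new)
    W <- cbind(W, hvp(t_new))
  }
  best
}

#' @rdname optimize_saddle
#' @param radius_init initial trust radius.
#' @param g_tol convergence threshold on max |gradient component|.
#' @param max_steps optimization step cap (default 1000).
#' @param project project rigid translations/rotations (default: on for
#'   multi-atom geometries).
#' @param qn_init_scale curvature scale of the quasi-Newton initial Hessian.
#' @param qn_davidson_init refine the initial quasi-Newton Hessian's
#'   leftmost direction by Davidson iteration (gradient calls are counted
#'   into the inclusive accounting).
#' @param qn_restart_after rebuild the quasi-Newton Hessian after this many
#'   consecutive steps whose improper ratio exceeds \code{ratio_high}.
#' @export
saddle_config <- function(radius_init = 0.1, g_tol = 1e-6,
                          max_steps = 1000L, project = NULL,
                          qn_init_scale = NULL, qn_davidson_init = TRUE,
                          qn_restart_after = 3L) {
  structure(list(radius_init = radius_init, g_tol = g_tol,
                 max_steps = as.integer(max_steps), project = project,
                 qn_init_scale = qn_init_scale,
                 qn_davidson_init = qn_davidson_init,
                 qn_restart_after = as.integer(qn_restart_after)),
            class = "saddle_config")
}

# exact Hessian availability: toy potentials and surrogates both provide it
.has_exact_hessian <- function(potential) {
  inherits(potential, "toy_potential") ||
    inherits(potential, "surrogate_model")
}

#' Optimize a first-order saddle point (transition state)
#'
#' RS-PRFO saddle search following the leftmost Hessian eigenmode at every
#' step, with trust-radius control.  Two Hessian sources are available:
#' \describe{
#'   \item{\code{"exact_every_step"}}{the exact analytic Hessian of the
#'     potential (toy surface or surrogate model) is recomputed at every
#'     step;}
#'   \item{\code{"qn"}}{a quasi-Newton Hessian: a curvature-scaled identity
#'     whose leftmost direction is refined by Davidson iteration from
#'     gradient calls, then propagated by TS-BFGS updates, and rebuilt when
#'     the quadratic model misbehaves for several consecutive steps.}
#' }
#' Gradient calls are accounted on two bases: \emph{exclusive} counts one
#' call per optimization step, \emph{inclusive} adds the finite-difference
#' gradient calls spent on Davidson initialization/reconstruction of
#' quasi-Newton Hessians.
#'
#' @param potential a \code{toy_potential} or \code{surrogate_model}.
#' @param guess starting \code{geometry}.
#' @param hessian_mode \code{"exact_every_step"} or \code{"qn"}.
#' @param config a \code{saddle_config}.
#' @return Object of class \code{"saddle_result"}: list with
#'   \code{converged}, \code{final_geometry}, \code{energy},
#'   \code{leftmost} (eigenvalue + eigenvector), \code{n_negative} (from the
#'   exact Hessian at the final point), \code{trace} (per-step data frame),
#'   \code{counts} (steps, gradient calls inclusive/exclusive, Hessian
#'   evaluations), \code{termination_reason}.
#' @examples
#' pot <- toy_potential("mueller_brown_2d")
#' sad <- find_stationary_oracle(pot, "saddle")[[1]]
#' guess <- perturb_guess(sad, sigma_pm = 5, seed = 2)
#' fit <- optimize_saddle(pot, guess)
#' fit$converged
#' @export
optimize_saddle <- function(potential, guess,
                            hessian_mode = c("exact_every_step", "qn"),
                            config = saddle_config()) {
  hessian_mode <- match.arg(hessian_mode)
  if (hessian_mode == "exact_every_step" && !.has_exact_hessian(potential))
    stop("potential provides no exact Hessian; use hessian_mode = 'qn'")
  project <- config$project
  if (is.null(project))
    project <- n_atoms(guess) > 1 && !inherits(potential,
                                               "pes_mueller_brown_2d")
  gradient_fn <- function(g) pes_eval(potential, g)$gradient
  trust <- trust_state(radius = config$radius_init)
  x <- coords_vector(guess)
  n <- length(x)
  geom <- function() set_coords(guess, x)
  g_excl <- 0L; g_incl_extra <- 0L; h_evals <- 0L
  qn_H <- NULL
  bad_streak <- 0L
  escapes <- 0L
  x_prev <- NULL

  qn_initial_hessian <- function(g0) {
    scale0 <- config$qn_init_scale
    if (config$qn_davidson_init) {
      dv <- davidson_leftmost(gradient_fn, g0, project = project)
      g_incl_extra <<- g_incl_extra + dv$gradient_calls
      if (is.null(scale0)) scale0 <- max(abs(dv$eigenvalue), 1)
      H0 <- scale0 * diag(n) +
        (dv$eigenvalue - scale0) * tcrossprod(dv$eigenvector)
    } else {
      if (is.null(scale0)) scale0 <- 1
      H0 <- scale0 * diag(n)
      H0[1, 1] <- -scale0   # give the search a downhill mode to follow
    }
    H0
  }

  trace <- vector("list", config$max_steps + 1L)
  xs <- vector("list", config$max_steps + 1L)
  converged <- FALSE
  reason <- "max_steps"
  ev <- pes_eval(potential, geom(),
                 hessian = hessian_mode == "exact_every_step")
  g_excl <- g_excl + 1L
  step_i <- 0L
  repeat {
    if (!is.finite(ev$energy)) { reason <- "energy_nan"; break }
    g <- ev$gradient
    P <- if (project) tr_projector(geom()) else NULL
    gp <- if (is.null(P)) g else as.numeric(P %*% g)
    trace[[step_i + 1L]] <- data.frame(
      step = step_i, energy = ev$energy, max_grad = max(abs(gp)),
      trust_radius = trust$radius,
      hessian_source = if (hessian_mode == "qn") "qn" else "exact")
    xs[[step_i + 1L]] <- x
    if (max(abs(gp)) <= config$g_tol) {
      # with exact Hessians the index is known: escape from stationary
      # points of the wrong index along the spurious mode
      if (hessian_mode == "exact_every_step" && escapes < 10L) {
        Hc <- ev$hessian
        if (!is.null(P)) Hc <- P %*% Hc %*% P
        mc <- normal_modes(hessian_matrix((Hc + t(Hc)) / 2,
                                          projected = project))
        if (mc$n_negative != 1L) {
          vals <- mc$eigenvalues
          zero <- abs(vals) <= 1e-6 * max(abs(vals), 1)
          kick_col <- if (mc$n_negative >= 2L)
            which(vals < 0 & !zero)[2L]
          else
            which(!zero & vals > 0)[1L]
          if (!is.na(kick_col)) {
            x <- x + trust$radius * mc$eigenvectors[, kick_col]
            ev <- pes_eval(potential, geom(), hessian = TRUE)
            g_excl <- g_excl + 1L
            escapes <- escapes + 1L
            step_i <- step_i + 1L
            next
          }
        }
      }
      converged <- TRUE
      reason <- "gradient_converged"; break
    }
    if (step_i >= config$max_steps) break

    if (hessian_mode == "exact_every_step") {
      H <- ev$hessian
      h_evals <- h_evals + 1L
    } else {
      if (is.null(qn_H)) qn_H <- qn_initial_hessian(geom())
      H <- qn_H
    }
    if (!is.null(P)) H <- P %*% H %*% P
    modes <- normal_modes(hessian_matrix((H + t(H)) / 2,
                                         projected = project))
    step <- prfo_step(gp, modes, trust)
    pred <- attr(step, "predicted_de")
    x_new <- x + step
    ev_new <- pes_eval(potential, set_coords(guess, x_new),
                       hessian = hessian_mode == "exact_every_step")
    g_excl <- g_excl + 1L
    if (!is.finite(ev_new$energy)) { reason <- "energy_nan"; break }
    actual <- ev_new$energy - ev$energy
    trust <- update_trust_radius(trust, pred, actual)
    # break period-2 limit cycles the ratio controller cannot see
    if (!is.null(x_prev) &&
        sqrt(sum((x_new - x_prev)^2)) < 1e-9 * max(1, sqrt(sum(x^2)))) {
      trust$radius <- max(trust$radius * trust$shrink, trust$radius_min)
    }
    x_prev <- x
    if (hessian_mode == "qn") {
      s_vec <- step
      y_vec <- ev_new$gradient - ev$gradient
      if (sqrt(sum(s_vec^2)) > 1e-12)
        qn_H <- ts_bfgs_update(qn_H, s_vec, y_vec)
      bad_streak <- if (is.infinite(attr(trust, "ratio")) ||
                        attr(trust, "ratio") > trust$ratio_high)
        bad_streak + 1L else 0L
      if (bad_streak >= config$qn_restart_after) {
        x <- x_new; ev <- ev_new
        qn_H <- qn_initial_hessian(geom())
        bad_streak <- 0L
        step_i <- step_i + 1L
        next
      }
    }
    x <- x_new; ev <- ev_new
    step_i <- step_i + 1L
  }

  final_geom <- geom()
  # characterize the final point with the exact Hessian when available
  n_negative <- NA_integer_
  leftmost <- NULL
  if (.has_exact_hessian(potential)) {
    Hf <- pes_eval(potential, final_geom, hessian = TRUE)$hessian
    if (project) {
      P <- tr_projector(final_geom)
      Hf <- P %*% Hf %*% P
    }
    mf <- normal_modes(hessian_matrix((Hf + t(Hf)) / 2,
                                      projected = project))
    n_negative <- mf$n_negative
    leftmost <- list(eigenvalue = mf$eigenvalues[1],
                     eigenvector = mf$eigenvectors[, 1])
  }
  structure(list(
    converged = converged,
    final_geometry = final_geom,
    energy = ev$energy,
    leftmost = leftmost,
    n_negative = n_negative,
    trace = do.call(rbind, trace[!vapply(trace, is.null, TRUE)]),
    trace_frames = lapply(xs[!vapply(xs, is.null, TRUE)],
                          function(v) matrix(v, ncol = 3, byrow = TRUE)),
    counts = list(steps = step_i,
                  gradient_calls_excl = g_excl,
                  gradient_calls_incl = g_excl + g_incl_extra,
                  hessian_evals = h_evals),
    hessian_mode = hessian_mode,
    termination_reason = reason),
    class = "saddle_result")
}

#' @export
print.saddle_result <- function(x, ...) {
  cat("<saddle_result>", if (x$converged) "converged" else
    paste0("NOT converged (", x$termination_reason, ")"),
    "in", x$counts$steps, "steps\n")
  cat("  energy", format(x$energy, digits = 10),
      " n_negative", x$n_negative,
      " max|grad|", format(utils::tail(x$trace$max_grad, 1), digits = 4),
      "\n")
  cat("  gradient calls:", x$counts$gradient_calls_excl, "(excl) /",
      x$counts$gradient_calls_incl, "(incl);",
      x$counts$hessian_evals, "Hessian evaluations\n")
  invisible(x)
}

#' @export
summary.saddle_result <- function(object, ...) {
  print(object)
  cat("  leftmost eigenvalue:",
      format(object$leftmost$eigenvalue, digits = 6), "\n")
  cat("  trust radius trajectory:",
      paste(format(range(object$trace$trust_radius), digits = 3),
            collapse = " .. "), "\n")
  invisible(object)
}

#' @export
plot.saddle_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$trace$step, x$trace$energy, type = "b", pch = 16,
                 xlab = "step", ylab = "energy", main = "energy", ...)
  graphics::plot(x$trace$step, x$trace$max_grad, type = "b", pch = 16,
                 log = "y", xlab = "step", ylab = "max |gradient|",
                 main = "convergence", ...)
  invisible(x)
}
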