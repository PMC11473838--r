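# Intrinsic reaction coordinate following: damped steepest descent in
# mass-weighted coordinates with a trust clamp (0.1 Angstrom amu^1/2 per
# step), from a displaced transition state down to the two connected
# minima, each endpoint polished by a trust-region quasi-Newton minimizer.

#' Displace a transition state along its imaginary mode
#'
#' Seeds an IRC branch: the TS is displaced by +/- magnitude along the
#' normalized leftmost (imaginary) eigenvector in mass-weighted coordinates,
#' then mapped back to Cartesian.
#'
#' @param ts a \code{geometry} at the transition state.
#' @param leftmost_vector Cartesian leftmost eigenvector.
#' @param leftmost_eigenvalue its eigenvalue; must be negative (a
#'   non-negative value is refused: the input is not a first-order saddle).
#' @param magnitude displacement in mass-weighted units
#'   (Angstrom amu^1/2), default 0.01.
#' @param sign +1 (forward) or -1 (backward).
#' @return the displaced \code{geometry}.
#' @export
initial_displacement <- function(ts, leftmost_vector, leftmost_eigenvalue,
                                 magnitude = 0.01, sign = 1) {
  if (leftmost_eigenvalue >= 0)
    stop("leftmost eigenvalue is non-negative: not a transition state")
  if (magnitude < 0) stop("magnitude must be non-negative")
  sm <- sqrt(mass_vector(ts))
  v_mw <- leftmost_vector * sm              # cartesian -> mass-weighted
  v_mw <- v_mw / sqrt(sum(v_mw^2))
  dx <- sign * magnitude * v_mw / sm        # back to cartesian
  set_coords(ts, coords_vector(ts) + dx)
}

#' Local minimization to a potential-energy minimum
#'
#' Trust-region quasi-Newton minimization (BFGS with a positive-definite
#' safeguard on the model eigenvalues) used to polish IRC endpoints.
#'
#' @param potential potential or surrogate model.
#' @param guess starting \code{geometry}.
#' @param g_tol convergence threshold on max |gradient component|.
#' @param max_steps step cap.
#' @param project remove rigid translations/rotations (default for
#'   multi-atom systems).
#' @return a \code{geometry} with attributes \code{energy},
#'   \code{converged}, \code{steps}.
#' @export
optimize_minimum <- function(potential, guess, g_tol = 1e-6,
                             max_steps = 1000L, project = NULL) {
  if (is.null(project))
    project <- n_atoms(guess) > 1 && !inherits(potential,
                                               "pes_mueller_brown_2d")
  x <- coords_vector(guess)
  n <- length(x)
  B <- diag(n)                       # model Hessian
  radius <- 0.1
  ev <- pes_eval(potential, set_coords(guess, x))
  converged <- FALSE
  steps <- 0L
  for (it in seq_len(max_steps)) {
    P <- if (project) tr_projector(set_coords(guess, x)) else NULL
    g <- if (is.null(P)) ev$gradient else as.numeric(P %*% ev$gradient)
    if (max(abs(g)) <= g_tol) { converged <- TRUE; break }
    Bp <- if (is.null(P)) B else P %*% B %*% P
    eg <- eigen((Bp + t(Bp)) / 2, symmetric = TRUE)
    vals <- pmax(eg$values, 1e-4 * max(abs(eg$values), 1)) # PD safeguard
    gq <- as.numeric(crossprod(eg$vectors, g))
    step <- -as.numeric(eg$vectors %*% (gq / vals))
    ns <- sqrt(sum(step^2))
    if (ns > radius) step <- step * radius / ns
    x_new <- x + step
    ev_new <- pes_eval(potential, set_coords(guess, x_new))
    if (!is.finite(ev_new$energy)) break
    if (ev_new$energy <= ev$energy + 1e-12 * abs(ev$energy)) {
      y <- ev_new$gradient - ev$gradient
      sy <- sum(step * y)
      if (sy > 1e-12) {
        Bs <- as.numeric(B %*% step)
        B <- B + tcrossprod(y, y) / sy -
          tcrossprod(Bs, Bs) / sum(step * Bs)
      }
      x <- x_new; ev <- ev_new
      radius <- min(radius * 1.2, 0.5)
      steps <- steps + 1L
    } else {
      radius <- max(radius * 0.25, 1e-8)
    }
  }
  out <- set_coords(guess, x)
  attr(out, "energy") <- ev$energy
  attr(out, "converged") <- converged
  attr(out, "steps") <- steps
  out
}

#' Follow one IRC branch by damped mass-weighted descent
#'
#' Steepest descent in mass-weighted coordinates with per-step displacement
#' clamped to the IRC trust radius (default 0.1 Angstrom amu^1/2).  Steps
#' that would raise the energy are halved and retried, so the recorded
#' energies are monotonically non-increasing; descent stops at the shared
#' gradient tolerance or the 1000-step cap, and the endpoint is polished by
#' \code{\link{optimize_minimum}}.
#'
#' @param potential potential or surrogate model.
#' @param start displaced geometry strictly downhill of the TS (from
#'   \code{\link{initial_displacement}}).
#' @param trust per-step mass-weighted displacement bound
#'   (Angstrom amu^1/2), default 0.1.
#' @param g_tol gradient convergence threshold (shared with the saddle
#'   optimizer's default).
#' @param max_steps cap on descent steps (default 1000).
#' @param direction label stored on the result.
#' @return Object of class \code{"irc_path"}: list with \code{frames}
#'   (list of geometries), \code{energies}, \code{arc_length} (cumulative
#'   mass-weighted length per frame), \code{endpoint} (polished geometry),
#'   \code{direction}, \code{converged}.
#' @export
follow_irc_branch <- function(potential, start, trust = 0.1, g_tol = 1e-6,
                              max_steps = 1000L, direction = "forward") {
  sm <- sqrt(mass_vector(start))
  x <- coords_vector(start)
  ev <- pes_eval(potential, set_coords(start, x))
  frames <- list(set_coords(start, x))
  energies <- ev$energy
  arc <- 0
  h <- trust                                 # adaptive damped step
  for (it in seq_len(max_steps)) {
    g <- ev$gradient
    if (max(abs(g)) <= g_tol) break
    g_mw <- g / sm                           # mass-weighted gradient
    gn <- sqrt(sum(g_mw^2))
    ok <- FALSE
    for (halve in 1:40) {
      d_mw <- -min(h, trust) * g_mw / gn
      x_new <- x + d_mw / sm
      ev_new <- pes_eval(potential, set_coords(start, x_new))
      if (is.finite(ev_new$energy) &&
          ev_new$energy <= energies[length(energies)] + 1e-9) {
        ok <- TRUE; break
      }
      h <- h / 2
    }
    if (!ok) break                           # persistent uphill: stop branch
    de <- energies[length(energies)] - ev_new$energy
    arc <- c(arc, arc[length(arc)] + sqrt(sum(d_mw^2)))
    x <- x_new; ev <- ev_new
    frames[[length(frames) + 1L]] <- set_coords(start, x)
    energies <- c(energies, ev$energy)
    # descent exhausted at this trust resolution: hand over to the polisher
    if (de < 1e-10) break
    h <- min(h * 1.5, trust)
  }
  endpoint <- optimize_minimum(potential, set_coords(start, x),
                               g_tol = g_tol, max_steps = max_steps)
  structure(list(frames = frames, energies = energies, arc_length = arc,
                 endpoint = endpoint, direction = direction,
                 converged = attr(endpoint, "converged")),
            class = "irc_path")
}

#' @export
print.irc_path <- function(x, ...) {
  cat("<irc_path>", x$direction, ":", length(x$frames), "frames, arc",
      format(max(x$arc_length), digits = 5), "A amu^1/2, endpoint E =",
      format(attr(x$endpoint, "energy"), digits = 8),
      if (isTRUE(x$converged)) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Follow the IRC in both directions from an optimized TS
#'
#' Convenience driver: verifies the input is a first-order saddle (via the
#' exact Hessian when available), displaces along +/- the imaginary mode and
#' follows both branches to their minima.
#'
#' @param potential potential or surrogate model.
#' @param ts TS geometry (e.g. \code{$final_geometry} of a converged
#'   \code{\link{optimize_saddle}} run), or a \code{saddle_result}.
#' @param magnitude initial displacement (Angstrom amu^1/2).
#' @inheritParams follow_irc_branch
#' @return list of class \code{"irc_pair"} with \code{forward},
#'   \code{backward} (two \code{irc_path}s) and \code{ts_energy}.
#' @export
follow_irc <- function(potential, ts, magnitude = 0.01, trust = 0.1,
                       g_tol = 1e-6, max_steps = 1000L) {
  if (inherits(ts, "saddle_result")) ts <- ts$final_geometry
  project <- n_atoms(ts) > 1 && !inherits(potential,
                                          "pes_mueller_brown_2d")
  Hf <- pes_eval(potential, ts, hessian = TRUE)$hessian
  if (project) {
    P <- tr_projector(ts)
    Hf <- P %*% Hf %*% P
  }
  md <- normal_modes(hessian_matrix((Hf + t(Hf)) / 2, projected = project))
  if (md$n_negative != 1L)
    stop("IRC requires a first-order saddle; Hessian index is ",
         md$n_negative)
  v <- md$eigenvectors[, 1]
  lam <- md$eigenvalues[1]
  fwd <- follow_irc_branch(potential,
    initial_displacement(ts, v, lam, magnitude, +1),
    trust = trust, g_tol = g_tol, max_steps = max_steps,
    direction = "forward")
  bwd <- follow_irc_branch(potential,
    initial_displacement(ts, v, lam, magnitude, -1),
    trust = trust, g_tol = g_tol, max_steps = max_steps,
    direction = "backward")
  structure(list(forward = fwd, backward = bwd,
                 ts_energy = pes_eval(potential, ts)$energy),
            class = "irc_pair")
}

#' @export
print.irc_pair <- function(x, ...) {
  cat("<irc_pair> TS energy", format(x$ts_energy, digits = 8), "\n  ")
  print(x$forward)
  cat("  ")
  print(x$backward)
  invisible(x)
}
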