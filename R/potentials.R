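#' Analytic toy potential-energy surfaces
#'
#' Constructs one of the package's analytic reactive surfaces.  Each surface
#' has closed-form energies, gradients and Hessians (exact to machine
#' precision) and serves both as an optimization target and as the exact
#' oracle against which learned Hessians and finite differences are checked.
#'
#' Available surfaces:
#' \describe{
#'   \item{\code{mueller_brown_2d}}{The standard four-Gaussian 2D test
#'     surface (three minima, two saddles), realized as a single
#'     structureless particle in 3D with a stiff harmonic tether on z
#'     (parameter \code{kz}) so that all code paths are uniformly
#'     3N-dimensional.  Energies in toy units, lengths in Angstrom.}
#'   \item{\code{morse_exchange_abc}}{A triatomic F-H-O bond-exchange
#'     surface: Morse bonds on F-H and H-O, an anti-bonding bond-order
#'     coupling \code{c_rep * n_FH * n_HO} (with \code{n = exp(-a (r - r0))})
#'     that makes simultaneous bonding unfavourable, and a shallow Morse-type
#'     van der Waals well on F-O.  It has an F-H bonded well, an H-O bonded
#'     well (different connectivity graphs) and a bond-exchange first-order
#'     saddle between them.}
#'   \item{\code{torsion_tetramer}}{A 4-atom carbon chain with stiff
#'     harmonic bonds, harmonic bending terms in cos(theta), and a torsional
#'     double well \code{v_bar * cos(phi)^2 * sin(theta1)^2 * sin(theta2)^2}
#'     (the polynomial dihedral form, smooth through collinear angles) whose
#'     minima (phi = +/-90 degrees) are mirror-image conformers: its saddles
#'     are conformational (isomorphic endpoint graphs).}
#' }
#'
#' @param name one of \code{"mueller_brown_2d"}, \code{"morse_exchange_abc"},
#'   \code{"torsion_tetramer"}.
#' @param params named list overriding documented default parameters (see
#'   \code{potential_params} on the returned object for the complete map).
#' @return An object of class \code{c("pes_<name>", "toy_potential")}.
#' @examples
#' pot <- toy_potential("mueller_brown_2d")
#' ev <- pes_eval(pot, reference_geometry(pot), hessian = TRUE)
#' ev$energy
#' @export
toy_potential <- function(name, params = list()) {
  defaults <- switch(name,
    mueller_brown_2d = list(
      A  = c(-200, -100, -170, 15),
      a  = c(-1, -1, -6.5, 0.7),
      b  = c(0, 0, 11, 0.6),
      cc = c(-10, -10, -6.5, 0.7),
      x0 = c(1, 0, -0.5, -1),
      y0 = c(0, 0.5, 1.5, 1),
      kz = 100),
    morse_exchange_abc = list(
      D = 100, a = 1.5, r0 = 0.96,     # bonding Morse wells (F-H, H-O)
      c_rep = 250,                     # bond-order coupling, > 2D for index-1
      Dv = 3, av = 1.0, rv = 2.8),     # shallow F-O vdW Morse
    torsion_tetramer = list(
      kb = 300, r0 = 1.5,              # harmonic bonds
      ka = 50, cos_theta0 = -1 / 3,    # bending, theta0 ~ 109.47 deg
      v_bar = 5),                      # torsional barrier, minima at +/-90
    stop("unknown potential name: ", name)
  )
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s) for ", name, ": ",
         paste(unknown, collapse = ", "))
  defaults[names(params)] <- params
  structure(list(name = name, params = defaults),
            class = c(paste0("pes_", name), "toy_potential"))
}

#' @export
print.toy_potential <- function(x, ...) {
  cat("<toy_potential>", x$name, "\n")
  str(x$params, give.attr = FALSE)
  invisible(x)
}

#' Complete parameter map of a potential
#' @param potential a \code{toy_potential}.
#' @return named list of all parameters (no implicit values).
#' @export
potential_params <- function(potential) potential$params

#' Canonical reference geometry for a potential
#'
#' A valid (not necessarily stationary) geometry with the right atom count,
#' elements and masses, used as a template for sampling and oracle searches.
#' @param potential a \code{toy_potential}.
#' @return a \code{geometry}.
#' @export
reference_geometry <- function(potential) {
  switch(potential$name,
    mueller_brown_2d = geometry("X", rbind(c(0, 0.5, 0)), masses = 1),
    morse_exchange_abc = geometry(c("F", "H", "O"),
      rbind(c(0, 0, 0), c(1.4, 0, 0), c(2.9, 0, 0))),
    torsion_tetramer = {
      p <- potential$params
      th <- acos(p$cos_theta0)
      # chain with ideal bonds/angles at a 90-degree dihedral
      b <- p$r0
      p1 <- c(0, 0, 0)
      p2 <- c(b, 0, 0)
      p3 <- p2 + b * c(-cos(th - pi / 2 * 0), 0, 0) # placed below via helper
      # build explicitly: angle at p2 between p1 and p3 equals th
      p3 <- p2 + b * c(cos(pi - th), sin(pi - th), 0)
      # p4: angle th at p3, dihedral +90
      p4 <- .place_fourth(p1, p2, p3, b, th, pi / 2)
      geometry(c("C", "C", "C", "C"), rbind(p1, p2, p3, p4))
    })
}

# place atom D with |CD| = r, angle BCD = theta, dihedral ABCD = phi
.place_fourth <- function(a, b, c_, r, theta, phi) {
  bc <- c_ - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- ab - sum(ab * bc) * bc
  n <- n / sqrt(sum(n^2))
  m <- c(bc[2] * n[3] - bc[3] * n[2],
         bc[3] * n[1] - bc[1] * n[3],
         bc[1] * n[2] - bc[2] * n[1])
  d <- -r * cos(theta) * bc +
    r * sin(theta) * (cos(phi) * (-n) + sin(phi) * m)
  c_ + d
}

#' Evaluate a potential at a geometry
#'
#' Returns the energy, the exact analytic gradient and (optionally) the exact
#' analytic Hessian.  For the toy surfaces all derivatives are closed-form or
#' propagated by exact second-order forward-mode arithmetic; nothing is a
#' finite difference.
#'
#' @param potential a \code{toy_potential} or \code{surrogate_model}.
#' @param geometry a \code{geometry} with the atom count the potential
#'   expects.
#' @param hessian logical; also compute the 3N x 3N analytic Hessian.
#' @return An object of class \code{"pes_eval"}: list with \code{energy}
#'   (scalar), \code{gradient} (length-3N numeric, energy / Angstrom) and
#'   \code{hessian} (3N x 3N symmetric matrix or NULL).
#' @export
pes_eval <- function(potential, geometry, hessian = FALSE) {
  UseMethod("pes_eval")
}

.check_atoms <- function(potential, geometry, n_expected) {
  if (n_atoms(geometry) != n_expected)
    stop("dimension error: ", potential$name, " expects ", n_expected,
         " atom(s), geometry has ", n_atoms(geometry))
}

.pes_eval_result <- function(energy, gradient, hessian = NULL) {
  if (!is.finite(energy)) stop("non-finite energy")
  if (!is.null(hessian)) hessian <- (hessian + t(hessian)) / 2
  structure(list(energy = energy, gradient = as.numeric(gradient),
                 hessian = hessian),
            class = "pes_eval")
}

#' @export
print.pes_eval <- function(x, ...) {
  cat("<pes_eval> energy =", format(x$energy, digits = 10),
      " max|grad| =", format(max(abs(x$gradient)), digits = 4),
      if (!is.null(x$hessian)) " (with hessian)" else "", "\n")
  invisible(x)
}

#' @export
pes_eval.pes_mueller_brown_2d <- function(potential, geometry,
                                          hessian = FALSE) {
  .check_atoms(potential, geometry, 1L)
  p <- potential$params
  x <- geometry$coords[1, 1]; y <- geometry$coords[1, 2]
  z <- geometry$coords[1, 3]
  dx <- x - p$x0; dy <- y - p$y0
  u <- p$a * dx^2 + p$b * dx * dy + p$cc * dy^2
  e <- p$A * exp(u)
  V <- sum(e) + 0.5 * p$kz * z^2
  ux <- 2 * p$a * dx + p$b * dy
  uy <- p$b * dx + 2 * p$cc * dy
  g <- c(sum(e * ux), sum(e * uy), p$kz * z)
  H <- NULL
  if (hessian) {
    H <- matrix(0, 3, 3)
    H[1, 1] <- sum(e * (ux^2 + 2 * p$a))
    H[2, 2] <- sum(e * (uy^2 + 2 * p$cc))
    H[1, 2] <- H[2, 1] <- sum(e * (ux * uy + p$b))
    H[3, 3] <- p$kz
  }
  .pes_eval_result(V, g, H)
}

# --- generic distance-based assembly ------------------------------------
# For V = g(r_1, ..., r_P) over pair distances, assemble Cartesian gradient
# and Hessian from dV/dr_p and d2V/dr_p dr_q:
#   grad = sum_p g_p grad(r_p)
#   hess = sum_p g_p hess(r_p) + sum_pq g_pq grad(r_p) grad(r_q)^T
.assemble_from_distances <- function(coords, pairs, g1, g2 = NULL) {
  n <- nrow(coords)
  P <- nrow(pairs)
  grads <- vector("list", P)   # each: 3n vector
  r <- numeric(P)
  for (p in seq_len(P)) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    dvec <- coords[i, ] - coords[j, ]
    r[p] <- sqrt(sum(dvec^2))
    u <- dvec / r[p]
    gr <- numeric(3 * n)
    gr[(3 * i - 2):(3 * i)] <- u
    gr[(3 * j - 2):(3 * j)] <- -u
    grads[[p]] <- gr
  }
  grad <- numeric(3 * n)
  for (p in seq_len(P)) grad <- grad + g1[p] * grads[[p]]
  H <- NULL
  if (!is.null(g2)) {
    H <- matrix(0, 3 * n, 3 * n)
    for (p in seq_len(P)) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      dvec <- coords[i, ] - coords[j, ]
      u <- dvec / r[p]
      blk <- (diag(3) - tcrossprod(u)) / r[p]    # hessian of r wrt one atom
      ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
      H[ii, ii] <- H[ii, ii] + g1[p] * blk
      H[jj, jj] <- H[jj, jj] + g1[p] * blk
      H[ii, jj] <- H[ii, jj] - g1[p] * blk
      H[jj, ii] <- H[jj, ii] - g1[p] * blk
      for (q in seq_len(P))
        H <- H + g2[p, q] * tcrossprod(grads[[p]], grads[[q]])
    }
  }
  list(r = r, gradient = grad, hessian = H)
}

#' @export
pes_eval.pes_morse_exchange_abc <- function(potential, geometry,
                                            hessian = FALSE) {
  .check_atoms(potential, geometry, 3L)
  p <- potential$params
  pairs <- rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L))   # F-H, H-O, F-O
  X <- geometry$coords
  r <- c(sqrt(sum((X[1, ] - X[2, ])^2)), sqrt(sum((X[2, ] - X[3, ])^2)),
         sqrt(sum((X[1, ] - X[3, ])^2)))
  n1 <- exp(-p$a * (r[1] - p$r0)); n2 <- exp(-p$a * (r[2] - p$r0))
  ev <- exp(-p$av * (r[3] - p$rv))
  # Morse(r) = D((1-n)^2 - 1) = D(n^2 - 2n); coupling c_rep n1 n2; vdW Morse
  V <- p$D * (n1^2 - 2 * n1) + p$D * (n2^2 - 2 * n2) +
    p$c_rep * n1 * n2 + p$Dv * (ev^2 - 2 * ev)
  dn1 <- -p$a * n1; dn2 <- -p$a * n2; dev <- -p$av * ev
  g1 <- c(p$D * (2 * n1 - 2) * dn1 + p$c_rep * dn1 * n2,
          p$D * (2 * n2 - 2) * dn2 + p$c_rep * n1 * dn2,
          p$Dv * (2 * ev - 2) * dev)
  g2 <- NULL
  if (hessian) {
    d2n1 <- p$a^2 * n1; d2n2 <- p$a^2 * n2; d2ev <- p$av^2 * ev
    g2 <- matrix(0, 3, 3)
    g2[1, 1] <- p$D * (2 * dn1^2 + (2 * n1 - 2) * d2n1) +
      p$c_rep * d2n1 * n2
    g2[2, 2] <- p$D * (2 * dn2^2 + (2 * n2 - 2) * d2n2) +
      p$c_rep * n1 * d2n2
    g2[3, 3] <- p$Dv * (2 * dev^2 + (2 * ev - 2) * d2ev)
    g2[1, 2] <- g2[2, 1] <- p$c_rep * dn1 * dn2
  }
  asm <- .assemble_from_distances(X, pairs, g1, g2)
  .pes_eval_result(V, asm$gradient, asm$hessian)
}

# torsion tetramer energy over hyper-dual coordinates
.torsion_energy_hd <- function(coords_hd, p) {
  at <- function(i) coords_hd[(3 * i - 2):(3 * i)]
  vsub <- function(u, v) lapply(1:3, function(k) hd_sub(u[[k]], v[[k]]))
  p1 <- at(1); p2 <- at(2); p3 <- at(3); p4 <- at(4)
  E <- hd(0)
  # bonds
  for (b in list(list(p1, p2), list(p2, p3), list(p3, p4))) {
    d <- vsub(b[[1]], b[[2]])
    r <- hd_norm3(d)
    dr <- hd_sub(r, p$r0)
    E <- hd_add(E, hd_mul(0.5 * p$kb, hd_sq(dr)))
  }
  # angles 1-2-3 and 2-3-4, harmonic in cos(theta)
  for (tr in list(list(p1, p2, p3), list(p2, p3, p4))) {
    u <- vsub(tr[[1]], tr[[2]]); v <- vsub(tr[[3]], tr[[2]])
    cth <- hd_div(hd_dot3(u, v), hd_mul(hd_norm3(u), hd_norm3(v)))
    E <- hd_add(E, hd_mul(0.5 * p$ka, hd_sq(hd_sub(cth, p$cos_theta0))))
  }
  # torsion double well with minima at +/- 90 degrees, in the polynomial
  # form v_bar (n1.n2)^2 / (|b1|^2 |b2|^4 |b3|^2) = v_bar cos^2(phi)
  # sin^2(theta1) sin^2(theta2): smooth through collinear angles (no 0/0),
  # keeping the surface C2 everywhere with nonzero bond lengths
  b1 <- vsub(p2, p1); b2 <- vsub(p3, p2); b3 <- vsub(p4, p3)
  m1 <- hd_cross3(b1, b2); m2 <- hd_cross3(b2, b3)
  num <- hd_sq(hd_dot3(m1, m2))
  den <- hd_mul(hd_mul(hd_dot3(b1, b1), hd_sq(hd_dot3(b2, b2))),
                hd_dot3(b3, b3))
  hd_add(E, hd_mul(p$v_bar, hd_div(num, den)))
}

#' @export
pes_eval.pes_torsion_tetramer <- function(potential, geometry,
                                          hessian = FALSE) {
  .check_atoms(potential, geometry, 4L)
  p <- potential$params
  out <- hd_evaluate(function(ch) .torsion_energy_hd(ch, p),
                     coords_vector(geometry), hessian = hessian)
  .pes_eval_result(out$energy, out$gradient, out$hessian)
}
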