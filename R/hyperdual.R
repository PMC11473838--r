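# Second-order forward-mode (hyper-dual) arithmetic.
#
# A hyper-dual number x = a + b*e1 + c*e2 + d*e1*e2 with e1^2 = e2^2 = 0
# propagates exact first and second derivatives through any composition of
# smooth primitives: f(x) has value f(a), e1/e2 parts f'(a)b / f'(a)c and
# cross part f'(a)d + f''(a)bc.  Components are numeric vectors so a whole
# batch of directional seeds (e.g. all Hessian entry pairs) is evaluated in
# one vectorized pass.  Internal: potentials whose closed-form second
# derivatives would be error-prone (angles, dihedrals) are written in terms
# of these primitives; the result is exact to machine precision, not a
# finite difference.

hd <- function(a, b = 0, c = 0, d = 0) {
  n <- max(length(a), length(b), length(c), length(d))
  list(a = rep_len(as.numeric(a), n), b = rep_len(as.numeric(b), n),
       c = rep_len(as.numeric(c), n), d = rep_len(as.numeric(d), n))
}

hd_is <- function(x) is.list(x) && !is.null(x$a) && !is.null(x$d)

hd_wrap <- function(x, n) if (hd_is(x)) x else hd(rep_len(as.numeric(x), n))

hd_add <- function(x, y) {
  n <- max(length(if (hd_is(x)) x$a else x), length(if (hd_is(y)) y$a else y))
  x <- hd_wrap(x, n); y <- hd_wrap(y, n)
  list(a = x$a + y$a, b = x$b + y$b, c = x$c + y$c, d = x$d + y$d)
}

hd_sub <- function(x, y) {
  n <- max(length(if (hd_is(x)) x$a else x), length(if (hd_is(y)) y$a else y))
  x <- hd_wrap(x, n); y <- hd_wrap(y, n)
  list(a = x$a - y$a, b = x$b - y$b, c = x$c - y$c, d = x$d - y$d)
}

hd_mul <- function(x, y) {
  n <- max(length(if (hd_is(x)) x$a else x), length(if (hd_is(y)) y$a else y))
  x <- hd_wrap(x, n); y <- hd_wrap(y, n)
  list(a = x$a * y$a,
       b = x$a * y$b + x$b * y$a,
       c = x$a * y$c + x$c * y$a,
       d = x$a * y$d + x$b * y$c + x$c * y$b + x$d * y$a)
}

hd_div <- function(x, y) {
  n <- max(length(if (hd_is(x)) x$a else x), length(if (hd_is(y)) y$a else y))
  x <- hd_wrap(x, n); y <- hd_wrap(y, n)
  inv_a <- 1 / y$a
  # chain rule through g(u) = 1/u: g' = -1/u^2, g'' = 2/u^3
  gb <- -inv_a^2 * y$b
  gc <- -inv_a^2 * y$c
  gd <- -inv_a^2 * y$d + 2 * inv_a^3 * y$b * y$c
  hd_mul(x, list(a = inv_a, b = gb, c = gc, d = gd))
}

# univariate smooth primitive with derivatives f, f', f''
hd_apply <- function(x, f, f1, f2) {
  fa <- f(x$a); f1a <- f1(x$a)
  list(a = fa, b = f1a * x$b, c = f1a * x$c,
       d = f1a * x$d + f2(x$a) * x$b * x$c)
}

hd_exp  <- function(x) hd_apply(x, exp, exp, exp)
hd_sqrt <- function(x) hd_apply(x, sqrt,
                                function(a) 0.5 / sqrt(a),
                                function(a) -0.25 / a^1.5)
hd_sq   <- function(x) hd_mul(x, x)

# dot product of two length-3 lists of hd scalars
hd_dot3 <- function(u, v) {
  hd_add(hd_add(hd_mul(u[[1]], v[[1]]), hd_mul(u[[2]], v[[2]])),
         hd_mul(u[[3]], v[[3]]))
}

hd_cross3 <- function(u, v) {
  list(hd_sub(hd_mul(u[[2]], v[[3]]), hd_mul(u[[3]], v[[2]])),
       hd_sub(hd_mul(u[[3]], v[[1]]), hd_mul(u[[1]], v[[3]])),
       hd_sub(hd_mul(u[[1]], v[[2]]), hd_mul(u[[2]], v[[1]])))
}

hd_norm3 <- function(u) hd_sqrt(hd_dot3(u, u))

# Evaluate energy, gradient and (optionally) Hessian of an energy function
# written over hyper-dual coordinates.  energy_hd receives a list of n hd
# scalars (one per Cartesian coordinate) and returns one hd scalar.
hd_evaluate <- function(energy_hd, x, hessian = FALSE) {
  n <- length(x)
  # gradient batch: seed b = e_i across n lanes, c = 0
  lanes_g <- diag(n)
  coords <- lapply(seq_len(n), function(k)
    hd(rep(x[k], n), b = lanes_g[k, ], c = 0, d = 0))
  eg <- energy_hd(coords)
  energy <- eg$a[1]
  gradient <- eg$b
  H <- NULL
  if (hessian) {
    pairs <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
    m <- nrow(pairs)
    bmat <- matrix(0, n, m); cmat <- matrix(0, n, m)
    bmat[cbind(pairs[, 1], seq_len(m))] <- 1
    cmat[cbind(pairs[, 2], seq_len(m))] <- 1
    coords <- lapply(seq_len(n), function(k)
      hd(rep(x[k], m), b = bmat[k, ], c = cmat[k, ], d = 0))
    eh <- energy_hd(coords)
    H <- matrix(0, n, n)
    H[cbind(pairs[, 1], pairs[, 2])] <- eh$d
    H[cbind(pairs[, 2], pairs[, 1])] <- eh$d
  }
  list(energy = energy, gradient = gradient, hessian = H)
}
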