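# A minimal C2-continuous learned surrogate potential.
#
# Per-atom radial features (Gaussian radial basis x polynomial cutoff,
# separate channels per neighbour element) feed a small shared SiLU network
# predicting per-atom energies; the molecular energy is their sum plus
# per-element biases.  Because every building block is closed-form and at
# least twice continuously differentiable, the gradient and Hessian of the
# predicted energy are computed as exact analytic derivatives (chain rule
# through the network and the pairwise feature map) -- the same quantities
# reverse-mode automatic differentiation would produce, with no finite
# differences anywhere.

# --- radial basis + cutoff ------------------------------------------------

# polynomial cutoff: value and first two derivatives vanish at r = rc
.cutoff_val <- function(r, rc) {
  t <- pmin(r / rc, 1)
  ifelse(r < rc, 1 - 10 * t^3 + 15 * t^4 - 6 * t^5, 0)
}
.cutoff_d1 <- function(r, rc) {
  t <- pmin(r / rc, 1)
  ifelse(r < rc, (-30 * t^2 + 60 * t^3 - 30 * t^4) / rc, 0)
}
.cutoff_d2 <- function(r, rc) {
  t <- pmin(r / rc, 1)
  ifelse(r < rc, (-60 * t + 180 * t^2 - 120 * t^3) / rc^2, 0)
}

# rho_k(r) and its first two derivatives for all k at a scalar distance
.rbf_all <- function(r, spec, deriv = 0L) {
  d <- r - spec$centers
  g <- exp(-spec$gamma * d^2)
  f <- .cutoff_val(r, spec$r_cut)
  if (deriv == 0L) return(list(v = g * f))
  g1 <- -2 * spec$gamma * d * g
  f1 <- .cutoff_d1(r, spec$r_cut)
  if (deriv == 1L) return(list(v = g * f, d1 = g1 * f + g * f1))
  g2 <- (4 * spec$gamma^2 * d^2 - 2 * spec$gamma) * g
  f2 <- .cutoff_d2(r, spec$r_cut)
  list(v = g * f, d1 = g1 * f + g * f1,
       d2 = g2 * f + 2 * g1 * f1 + g * f2)
}

#' Radial feature specification
#'
#' @param elements character vector of element symbols the model knows
#'   (one radial channel per neighbour element).
#' @param n_rbf number of Gaussian radial basis functions (default 20).
#' @param r_cut polynomial cutoff radius in Angstrom (default 5); the cutoff
#'   function and its first two derivatives vanish at \code{r_cut}, keeping
#'   the model C2 continuous through the cutoff.
#' @return object of class \code{"feature_spec"}.
#' @export
feature_spec <- function(elements, n_rbf = 20L, r_cut = 5.0) {
  if (r_cut <= 0) stop("cutoff must be positive")
  elements <- sort(unique(as.character(elements)))
  centers <- seq(0, r_cut, length.out = n_rbf)
  structure(list(elements = elements, n_rbf = as.integer(n_rbf),
                 r_cut = r_cut, centers = centers,
                 gamma = 0.5 / diff(centers[1:2])^2,
                 n_features = as.integer(n_rbf) * length(elements)),
            class = "feature_spec")
}

.feat_cols <- function(spec, element) {
  e <- match(element, spec$elements)
  if (is.na(e)) stop("element ", element, " unknown to the feature spec")
  ((e - 1L) * spec$n_rbf + 1L):(e * spec$n_rbf)
}

#' Per-atom radial features of a geometry
#'
#' Each atom's feature vector is the sum over neighbours, per neighbour
#' element channel, of Gaussian radial basis functions damped by the
#' polynomial cutoff.  Atoms farther than the cutoff from every neighbour
#' have exactly zero features.
#'
#' @param geometry a \code{geometry}.
#' @param spec a \code{feature_spec}.
#' @return numeric N x n_features matrix.
#' @export
featurize <- function(geometry, spec) {
  n <- n_atoms(geometry)
  X <- matrix(0, n, spec$n_features)
  if (n < 2) return(X)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- atom_distance(geometry, i, j)
    if (r >= spec$r_cut) next
    v <- .rbf_all(r, spec)$v
    ci <- .feat_cols(spec, geometry$elements[j])
    cj <- .feat_cols(spec, geometry$elements[i])
    X[i, ci] <- X[i, ci] + v
    X[j, cj] <- X[j, cj] + v
  }
  X
}

# --- activations ----------------------------------------------------------

.act_fns <- function(activation) {
  switch(activation,
    silu = list(
      f  = function(z) z / (1 + exp(-z)),
      d1 = function(z) { s <- 1 / (1 + exp(-z)); s * (1 + z * (1 - s)) },
      d2 = function(z) { s <- 1 / (1 + exp(-z))
                         s * (1 - s) * (2 + z * (1 - 2 * s)) },
      c2 = TRUE),
    relu = list(
      f  = function(z) pmax(z, 0),
      d1 = function(z) (z > 0) * 1,     # keeps matrix shape
      d2 = function(z) 0 * z,
      c2 = FALSE),
    stop("unknown activation: ", activation))
}

# --- model container ------------------------------------------------------

.new_surrogate <- function(spec, params, norm, activation, e_scale,
                           metadata) {
  structure(list(spec = spec, params = params, norm = norm,
                 activation = activation, e_scale = e_scale,
                 metadata = metadata),
            class = "surrogate_model")
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat("<surrogate_model>", length(x$spec$elements), "element(s) [",
      paste(x$spec$elements, collapse = " "), "],",
      x$spec$n_rbf, "RBF, cutoff", x$spec$r_cut, "A, hidden",
      length(x$params$b1), paste0("(", x$activation, ")"), "\n")
  if (!is.null(x$metadata$final_val_loss))
    cat("  final validation loss:",
        format(x$metadata$final_val_loss, digits = 6),
        "after", x$metadata$epochs_run, "epochs\n")
  invisible(x)
}

# per-atom forward pass: returns z, a, s1, s2 given normalized features
# Xn (n_atoms x F)
.forward_atoms <- function(model, Xn, deriv = 2L) {
  act <- .act_fns(model$activation)
  Z <- model$params$W1 %*% t(Xn) + model$params$b1   # H x n_atoms
  out <- list(Z = Z, A = act$f(Z))
  if (deriv >= 1L) out$S1 <- act$d1(Z)
  if (deriv >= 2L) out$S2 <- act$d2(Z)
  out
}

.normalize_features <- function(model, X) {
  sweep(sweep(X, 2, model$norm$mean), 2, model$norm$sd, "/")
}

# Jacobian of atom i's raw features wrt all coordinates: F x 3N.
# Also returns pair bookkeeping reused by the Hessian assembly.
.feature_jacobians <- function(geometry, spec) {
  n <- n_atoms(geometry)
  J <- lapply(seq_len(n), function(i) matrix(0, spec$n_features, 3 * n))
  pairs <- list()
  if (n >= 2) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- atom_distance(geometry, i, j)
    if (r >= spec$r_cut) next
    rb <- .rbf_all(r, spec, deriv = 2L)
    u <- (geometry$coords[i, ] - geometry$coords[j, ]) / r
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    ci <- .feat_cols(spec, geometry$elements[j])
    cj <- .feat_cols(spec, geometry$elements[i])
    J[[i]][ci, ii] <- J[[i]][ci, ii] + outer(rb$d1, u)
    J[[i]][ci, jj] <- J[[i]][ci, jj] - outer(rb$d1, u)
    J[[j]][cj, jj] <- J[[j]][cj, jj] - outer(rb$d1, u)
    J[[j]][cj, ii] <- J[[j]][cj, ii] + outer(rb$d1, u)
    pairs[[length(pairs) + 1L]] <-
      list(i = i, j = j, r = r, u = u, rb = rb, ci = ci, cj = cj)
  }
  list(J = J, pairs = pairs)
}

#' Predict energy and gradient from a surrogate model
#'
#' The gradient is the exact analytic derivative of the predicted energy
#' (chain rule through the network and the pairwise feature map); predicted
#' forces are its negative.
#'
#' @param model a \code{surrogate_model}.
#' @param geometry a \code{geometry}.
#' @return a \code{pes_eval} (energy + gradient).
#' @export
predict_ef <- function(model, geometry) {
  pes_eval(model, geometry, hessian = FALSE)
}

#' @export
pes_eval.surrogate_model <- function(potential, geometry, hessian = FALSE) {
  model <- potential
  spec <- model$spec
  X <- featurize(geometry, spec)
  Xn <- .normalize_features(model, X)
  fw <- .forward_atoms(model, Xn, deriv = if (hessian) 2L else 1L)
  w2 <- model$params$w2
  bias <- sum(model$params$bias[match(geometry$elements, spec$elements)])
  energy <- model$e_scale * sum(crossprod(fw$A, w2)) + bias

  fj <- .feature_jacobians(geometry, spec)
  n3 <- 3L * n_atoms(geometry)
  inv_sd <- 1 / model$norm$sd
  # u_i = dE/d(raw features of atom i), F-vector
  U <- lapply(seq_len(n_atoms(geometry)), function(i) {
    model$e_scale * inv_sd *
      as.numeric(crossprod(model$params$W1, w2 * fw$S1[, i]))
  })
  grad <- numeric(n3)
  for (i in seq_along(U)) grad <- grad + as.numeric(crossprod(fj$J[[i]], U[[i]]))

  H <- NULL
  if (hessian) {
    if (!.act_fns(model$activation)$c2)
      stop("activation '", model$activation, "' is not twice continuously ",
           "differentiable; analytic Hessians require a C2 model")
    H <- matrix(0, n3, n3)
    W1 <- model$params$W1
    for (i in seq_along(U)) {
      Jn <- fj$J[[i]] * inv_sd          # normalized-feature jacobian
      Ki <- W1 %*% Jn                   # H x 3N
      D <- w2 * fw$S2[, i]
      H <- H + model$e_scale * crossprod(Ki, Ki * D)
    }
    # second derivatives of the features themselves
    for (p in fj$pairs) {
      w_r1 <- sum(U[[p$i]][p$ci] * p$rb$d1) + sum(U[[p$j]][p$cj] * p$rb$d1)
      w_r2 <- sum(U[[p$i]][p$ci] * p$rb$d2) + sum(U[[p$j]][p$cj] * p$rb$d2)
      blk <- w_r2 * tcrossprod(p$u) +
        w_r1 * (diag(3) - tcrossprod(p$u)) / p$r
      ii <- (3 * p$i - 2):(3 * p$i); jj <- (3 * p$j - 2):(3 * p$j)
      H[ii, ii] <- H[ii, ii] + blk
      H[jj, jj] <- H[jj, jj] + blk
      H[ii, jj] <- H[ii, jj] - blk
      H[jj, ii] <- H[jj, ii] - blk
    }
  }
  .pes_eval_result(energy, grad, H)
}

#' Exact analytic Hessian of the surrogate energy
#'
#' Computes the full second derivative of the predicted energy with respect
#' to Cartesian coordinates by differentiating the model a second time
#' (network input-Hessian plus feature curvature terms).  Refuses to run for
#' models configured with an activation that is not twice continuously
#' differentiable.
#'
#' @param model a \code{surrogate_model}.
#' @param geometry a \code{geometry}.
#' @return symmetric 3N x 3N matrix.
#' @export
hessian_autodiff <- function(model, geometry) {
  pes_eval(model, geometry, hessian = TRUE)$hessian
}

#' @export
predict.surrogate_model <- function(object, geometry,
                                    derivatives = c("gradient", "energy",
                                                    "hessian"), ...) {
  derivatives <- match.arg(derivatives)
  ev <- pes_eval(object, geometry, hessian = derivatives == "hessian")
  switch(derivatives, energy = ev$energy, gradient = ev, hessian = ev)
}
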