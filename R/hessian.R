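#' Hessian matrix container
#'
#' Wraps a symmetric 3N x 3N second-derivative matrix with its coordinate
#' frame (\code{"cartesian"} or \code{"mass_weighted"}) and a flag recording
#' whether rigid translations/rotations have been projected out.
#'
#' @param matrix numeric square matrix (symmetrized on construction; input
#'   asymmetry beyond 1e-8 of its scale is an error).
#' @param frame \code{"cartesian"} or \code{"mass_weighted"}.
#' @param projected logical: translations/rotations removed.
#' @param masses masses recorded when mass-weighted.
#' @param gradient_calls number of gradient evaluations spent constructing
#'   the matrix (0 for analytic Hessians).
#' @return object of class \code{"hessian_matrix"}.
#' @export
hessian_matrix <- function(matrix, frame = c("cartesian", "mass_weighted"),
                           projected = FALSE, masses = NULL,
                           gradient_calls = 0L) {
  frame <- match.arg(frame)
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stop("hessian must be square")
  asym <- max(abs(matrix - t(matrix)))
  if (asym > 1e-8 * max(1, max(abs(matrix))))
    stop("input matrix is not symmetric (max asymmetry ", asym, ")")
  if (frame == "mass_weighted" && is.null(masses))
    stop("mass_weighted hessian requires masses")
  structure(list(matrix = (matrix + t(matrix)) / 2, frame = frame,
                 projected = projected, masses = masses,
                 gradient_calls = as.integer(gradient_calls)),
            class = "hessian_matrix")
}

#' @export
print.hessian_matrix <- function(x, ...) {
  cat("<hessian_matrix>", nrow(x$matrix), "x", ncol(x$matrix),
      x$frame, if (x$projected) "(TR projected)" else "", "\n")
  invisible(x)
}

as_hessian <- function(H, ...) {
  if (inherits(H, "hessian_matrix")) H else hessian_matrix(H, ...)
}

#' Central finite-difference Hessian from a gradient function
#'
#' Builds the 3N x 3N Hessian by central differences of the gradient along
#' each Cartesian axis (step default 1e-4 Angstrom), symmetrized as
#' (H + t(H))/2.  The number of gradient calls (6N... exactly 2 per
#' coordinate) is recorded on the result.
#'
#' @param gradient_fn function(geometry) -> numeric 3N gradient.
#' @param geometry a \code{geometry}.
#' @param step displacement (Angstrom), default 1e-4.
#' @return a \code{hessian_matrix} (cartesian frame) with
#'   \code{gradient_calls = 6N}.
#' @export
finite_difference_hessian <- function(gradient_fn, geometry, step = 1e-4) {
  if (step <= 0) stop("step must be positive")
  x0 <- coords_vector(geometry)
  n <- length(x0)
  H <- matrix(0, n, n)
  calls <- 0L
  for (k in seq_len(n)) {
    xp <- x0; xp[k] <- xp[k] + step
    xm <- x0; xm[k] <- xm[k] - step
    gp <- gradient_fn(set_coords(geometry, xp))
    gm <- gradient_fn(set_coords(geometry, xm))
    calls <- calls + 2L
    if (!all(is.finite(gp)) || !all(is.finite(gm)))
      stop("non-finite gradient at displaced geometry (coordinate ", k, ")")
    H[, k] <- (gp - gm) / (2 * step)
  }
  hessian_matrix((H + t(H)) / 2, frame = "cartesian",
                 gradient_calls = calls)
}

# Orthonormal basis of rigid translations (and rotations about the centre of
# mass) at a geometry, in the given frame.  Rank-revealing so linear
# molecules (2 rotations) are handled automatically.
tr_basis <- function(geometry, mass_weighted = FALSE) {
  X <- geometry$coords
  n <- nrow(X)
  m <- geometry$masses
  com <- colSums(X * m) / sum(m)
  Xc <- sweep(X, 2, com)
  B <- matrix(0, 3 * n, 6)
  for (k in 1:3) B[seq(k, 3 * n, by = 3), k] <- 1          # translations
  for (i in seq_len(n)) {                                   # rotations
    r <- Xc[i, ]
    rows <- (3 * i - 2):(3 * i)
    B[rows, 4] <- c(0, -r[3], r[2])
    B[rows, 5] <- c(r[3], 0, -r[1])
    B[rows, 6] <- c(-r[2], r[1], 0)
  }
  if (mass_weighted) B <- B * sqrt(rep(m, each = 3))
  qr_B <- qr(B)
  rank <- sum(abs(diag(qr.R(qr_B))) > 1e-8 * max(abs(B), 1))
  qr.Q(qr_B)[, seq_len(rank), drop = FALSE]
}

# Projector onto the complement of the translation/rotation space.
tr_projector <- function(geometry, mass_weighted = FALSE) {
  Q <- tr_basis(geometry, mass_weighted)
  diag(nrow(Q)) - tcrossprod(Q)
}

#' Mass-weight and/or project a Cartesian Hessian
#'
#' Transforms H to mass-weighted coordinates, H' = M^(-1/2) H M^(-1/2), and
#' optionally projects out the rigid translation and rotation directions so
#' their eigenvalues are exactly zero.  Linear molecules (2 rotations) are
#' detected automatically from the geometry.
#'
#' @param H a \code{hessian_matrix} in the cartesian frame, or a plain
#'   matrix.
#' @param geometry the \code{geometry} the Hessian was evaluated at (supplies
#'   masses and the rotation generators).
#' @param mass_weight logical; apply M^(-1/2) scaling.
#' @param remove_tr logical; project out translations/rotations.
#' @return a \code{hessian_matrix} in the requested frame.
#' @export
mass_weight_and_project <- function(H, geometry, mass_weight = TRUE,
                                    remove_tr = TRUE) {
  H <- as_hessian(H)
  if (H$frame != "cartesian")
    stop("input hessian must be in the cartesian frame")
  M <- H$matrix
  mv <- mass_vector(geometry)
  if (length(mv) != nrow(M))
    stop("dimension mismatch between hessian and geometry")
  if (mass_weight) {
    s <- 1 / sqrt(mv)
    M <- M * tcrossprod(s)
  }
  if (remove_tr) {
    P <- tr_projector(geometry, mass_weighted = mass_weight)
    M <- P %*% M %*% P
  }
  hessian_matrix((M + t(M)) / 2,
                 frame = if (mass_weight) "mass_weighted" else "cartesian",
                 projected = remove_tr,
                 masses = if (mass_weight) geometry$masses else NULL,
                 gradient_calls = H$gradient_calls)
}

#' Normal modes of a Hessian
#'
#' Dense symmetric eigendecomposition with a deterministic convention:
#' eigenvalues ascending, each eigenvector's largest-magnitude component made
#' positive.  Frequencies are reported as sign(lambda) * sqrt(|lambda|)
#' (signed; a negative value encodes an imaginary frequency).  For a
#' mass-weighted Hessian in kcal mol^-1 Angstrom^-2 amu^-1 the conversion to
#' wavenumbers is freq_cm1 = 108.587 * sign(lambda) * sqrt(|lambda|)
#' (the single documented unit constant, exposed as
#' \code{attr(modes, "cm1_per_sqrt_unit")}).
#'
#' @param H a \code{hessian_matrix} or symmetric matrix.
#' @param zero_tol eigenvalues with |lambda| <= zero_tol are counted as
#'   numerically zero (projected translation/rotation modes).
#' @return object of class \code{"mode_set"}: list with \code{eigenvalues}
#'   (ascending), \code{eigenvectors} (orthonormal columns), \code{frequencies}
#'   (signed sqrt units), \code{n_negative}, \code{n_zero}.
#' @export
normal_modes <- function(H, zero_tol = 1e-6) {
  H <- as_hessian(H)
  eg <- eigen(H$matrix, symmetric = TRUE)
  ord <- order(eg$values)
  vals <- eg$values[ord]
  vecs <- eg$vectors[, ord, drop = FALSE]
  for (k in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, k]))
    if (vecs[i, k] < 0) vecs[, k] <- -vecs[, k]
  }
  scale <- max(abs(vals), 1)
  zero <- abs(vals) <= zero_tol * scale
  structure(list(
    eigenvalues = vals,
    eigenvectors = vecs,
    frequencies = structure(sign(vals) * sqrt(abs(vals)),
                            cm1_per_sqrt_unit = 108.587),
    n_negative = sum(vals < 0 & !zero),
    n_zero = sum(zero),
    frame = H$frame, projected = H$projected),
    class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat("<mode_set>", length(x$eigenvalues), "modes;",
      x$n_negative, "negative,", x$n_zero, "~zero;",
      "leftmost =", format(x$eigenvalues[1], digits = 6), "\n")
  invisible(x)
}

# --- linear sum assignment (Hungarian, shortest augmenting path) ---------
# Minimizes sum_i cost[i, assign[i]] over permutations.  O(n^3).  Written
# here because no assignment solver ships with the environment's R stack;
# verified against brute-force enumeration in the tests.
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  if (ncol(cost) != n) stop("cost matrix must be square")
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)           # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L                    # columns are offset by 1 (index 1 = virtual)
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
    p[1] <- 0L
  }
  assign_row <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) assign_row[p[j]] <- j - 1L
  assign_row
}

#' Compare two Hessians by eigenpair assignment
#'
#' Diagonalizes both matrices, pairs predicted modes with reference modes by
#' solving the linear sum assignment problem on the cost
#' \code{1 - |cos(v_pred, v_ref)|}, and reports the eigenvalue RMSE over
#' assigned pairs, the mean absolute cosine similarity (MCS), and the
#' leftmost-eigenpair errors (using the assignment partner of the reference
#' leftmost mode).  Cosines are taken in absolute value since eigenvector
#' sign is arbitrary.
#'
#' @param predicted,reference \code{hessian_matrix} objects (or plain
#'   symmetric matrices) of equal dimension and frame.
#' @return object of class \code{"hessian_comparison"}: list with
#'   \code{eigenvalue_rmse}, \code{mean_cosine_similarity},
#'   \code{leftmost_eigenvalue_error} (signed, predicted - reference),
#'   \code{leftmost_cosine}, \code{assignment} (permutation: reference mode k
#'   is paired with predicted mode assignment[k]).
#' @export
compare_hessians <- function(predicted, reference) {
  predicted <- as_hessian(predicted); reference <- as_hessian(reference)
  if (!all(dim(predicted$matrix) == dim(reference$matrix)))
    stop("dimension mismatch")
  if (predicted$frame != reference$frame)
    stop("hessians are in different frames")
  mp <- normal_modes(predicted); mr <- normal_modes(reference)
  absc <- abs(crossprod(mr$eigenvectors, mp$eigenvectors)) # [ref, pred]
  assignment <- solve_assignment(1 - absc)
  cosines <- absc[cbind(seq_along(assignment), assignment)]
  dval <- mp$eigenvalues[assignment] - mr$eigenvalues
  structure(list(
    eigenvalue_rmse = sqrt(mean(dval^2)),
    mean_cosine_similarity = mean(cosines),
    leftmost_eigenvalue_error = dval[1],
    leftmost_cosine = cosines[1],
    assignment = assignment),
    class = "hessian_comparison")
}

#' @export
print.hessian_comparison <- function(x, ...) {
  cat("<hessian_comparison> eigenvalue RMSE =",
      format(x$eigenvalue_rmse, digits = 6),
      " MCS =", format(x$mean_cosine_similarity, digits = 6), "\n",
      "leftmost: d(lambda) =",
      format(x$leftmost_eigenvalue_error, digits = 6),
      " |cos| =", format(x$leftmost_cosine, digits = 6), "\n")
  invisible(x)
}

#' Write / read a Hessian as plain text
#'
#' Serializes the matrix as a whitespace-separated array with a one-line
#' header comment recording frame and projection metadata.
#' @param H a \code{hessian_matrix}.
#' @param path file path.
#' @return \code{write_hessian}: invisibly, the path.  \code{read_hessian}:
#'   the \code{hessian_matrix}.
#' @export
write_hessian <- function(H, path) {
  H <- as_hessian(H)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hesstate hessian frame=%s projected=%s n=%d",
                     H$frame, H$projected, nrow(H$matrix)), con)
  utils::write.table(format(H$matrix, digits = 17), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hessian
#' @export
read_hessian <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("^# hesstate hessian", header))
    stop("not a hesstate hessian file: ", path)
  kv <- regmatches(header, gregexpr("[a-z]+=[^ ]+", header))[[1]]
  meta <- stats::setNames(sub(".*=", "", kv), sub("=.*", "", kv))
  M <- as.matrix(utils::read.table(path, skip = 1L))
  dimnames(M) <- NULL
  hessian_matrix(M, frame = meta[["frame"]],
                 projected = as.logical(meta[["projected"]]))
}
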