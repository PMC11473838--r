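#' Optimal proper-rotation superposition (Kabsch)
#'
#' Finds the proper rotation (determinant +1; reflections excluded) and
#' translation that minimize the RMSD between two conformations, and returns
#' the aligned coordinates of \code{x} superposed onto \code{ref}.
#'
#' @param x,ref numeric N x 3 coordinate matrices with consistent atom order.
#' @param weights optional per-atom weights (e.g. masses); default uniform.
#' @return list with \code{coords} (aligned copy of \code{x}), \code{rmsd},
#'   \code{rotation} (3 x 3, det +1) and \code{distance}
#'   (weighted Cartesian distance \eqn{\sqrt{\sum_i w_i |x_i - ref_i|^2}}
#'   after alignment).
#' @export
kabsch_align <- function(x, ref, weights = NULL) {
  x <- as.matrix(x); ref <- as.matrix(ref)
  if (!all(dim(x) == dim(ref)) || ncol(x) != 3L)
    stop("frame shape mismatch: need equal N x 3 matrices")
  n <- nrow(x)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  wn <- w / sum(w)
  cx <- colSums(x * wn); cr <- colSums(ref * wn)
  xc <- sweep(x, 2, cx); rc <- sweep(ref, 2, cr)
  A <- t(xc * w) %*% rc
  sv <- svd(A)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  aligned <- sweep(xc %*% t(R), 2, cr, "+")
  dist2 <- sum(w * rowSums((aligned - ref)^2))
  list(coords = aligned,
       rmsd = sqrt(dist2 / sum(w)),
       rotation = R,
       distance = sqrt(dist2))
}

#' Alignment-corrected RMSD between two conformations
#' @inheritParams kabsch_align
#' @return scalar RMSD (Angstrom) after optimal proper-rotation alignment.
#' @export
kabsch_rmsd <- function(x, ref, weights = NULL) {
  kabsch_align(x, ref, weights)$rmsd
}
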