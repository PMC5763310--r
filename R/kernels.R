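#' Gaussian (RBF) kernel between the columns of a data matrix
#'
#' Computes the kernel matrix `W` with entries
#' `W[a, b] = exp(-||x_a - x_b||^2 / (2 * sigma^2))` between all pairs of
#' samples, where samples are the *columns* of `X` (features are rows, the
#' usual layout for omics matrices).
#'
#' When `bandwidth = "median"` the bandwidth sigma is set to the median of
#' the pairwise Euclidean distances between samples (the "median heuristic"),
#' which is scale-free and deterministic given the data.
#'
#' @param X numeric matrix, features x samples (at least 2 samples).
#' @param bandwidth positive numeric bandwidth sigma, or the string
#'   `"median"` for the median heuristic.
#' @return An n x n symmetric positive semidefinite matrix with unit
#'   diagonal, where n is the number of columns of `X`.
#' @examples
#' X <- matrix(c(0, 1), nrow = 1)
#' gaussian_kernel(X, bandwidth = 1)[1, 2]  # exp(-0.5)
#' @export
gaussian_kernel <- function(X, bandwidth = "median") {
  X <- as.matrix(X)
  if (ncol(X) < 2L) {
    stop("'X' must have at least 2 samples (columns)")
  }
  if (!all(is.finite(X))) {
    stop("'X' contains non-finite entries")
  }
  d <- as.matrix(stats::dist(t(X)))
  if (identical(bandwidth, "median")) {
    sigma <- stats::median(d[upper.tri(d)])
    if (!is.finite(sigma) || sigma <= 0) {
      stop("median-heuristic bandwidth is degenerate (all samples identical?)")
    }
  } else {
    sigma <- as.numeric(bandwidth)
    if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
      stop("'bandwidth' must be a single positive number or \"median\"")
    }
  }
  W <- exp(-d^2 / (2 * sigma^2))
  # exact symmetry and unit diagonal regardless of rounding in dist()
  W <- (W + t(W)) / 2
  diag(W) <- 1
  dimnames(W) <- if (!is.null(colnames(X))) list(colnames(X), colnames(X))
  attr(W, "bandwidth") <- sigma
  W
}

#' Median-heuristic kernel bandwidth
#'
#' The median of all pairwise Euclidean distances between the columns of
#' `X`; the default bandwidth used by [gaussian_kernel()].
#'
#' @param X numeric matrix, features x samples.
#' @return A single positive number.
#' @export
median_bandwidth <- function(X) {
  d <- stats::dist(t(as.matrix(X)))
  stats::median(d)
}

#' Normalize rows (or columns) to zero mean and unit Euclidean norm
#'
#' Each row (default) is centered to mean zero and scaled to Euclidean norm
#' one. This is the feature normalization applied to every block of the
#' simulated two-view datasets before stacking; with `margin = "column"`
#' the same operation is applied feature-wise to columns instead.
#'
#' @param X numeric matrix.
#' @param margin `"row"` (default) or `"column"`.
#' @param eps rows with centered norm below `eps` are an error (a constant
#'   row carries no information and cannot be normalized).
#' @return A matrix of the same shape as `X`.
#' @export
normalize_features <- function(X, margin = c("row", "column"), eps = 1e-12) {
  margin <- match.arg(margin)
  X <- as.matrix(X)
  if (margin == "column") {
    return(t(normalize_features(t(X), margin = "row", eps = eps)))
  }
  Xc <- X - rowMeans(X)
  nrm <- sqrt(rowSums(Xc^2))
  bad <- which(nrm < eps)
  if (length(bad) > 0L) {
    stop("row(s) ", paste(bad, collapse = ", "),
         " are constant and cannot be normalized to unit norm")
  }
  Xc / nrm
}

#' Centering matrix H = I - ee'/n
#'
#' Materializes the projection that removes the mean component of a vector.
#' `H` is symmetric and idempotent and annihilates the constant vector.
#' Internally the package never forms `H` for centering (see
#' [center_kernel()]); this constructor exists for reference and testing.
#'
#' @param n dimension.
#' @return An n x n matrix.
#' @export
centering_matrix <- function(n) {
  diag(n) - matrix(1 / n, n, n)
}

#' Double-center a kernel matrix: H K H
#'
#' Applies the centering projection on both sides without materializing H,
#' using rank-one corrections: `HKH = K - 1 r' - c 1' + g`, with r/c the
#' row/column means and g the grand mean. For symmetric K the result is
#' symmetric.
#'
#' @param K square numeric matrix.
#' @return The doubly centered matrix, same dimension as `K`.
#' @export
center_kernel <- function(K) {
  rm <- rowMeans(K)
  cm <- colMeans(K)
  gm <- mean(K)
  K - outer(rm, rep(1, ncol(K))) - outer(rep(1, nrow(K)), cm) + gm
}

#' Empirical HSIC agreement between two kernels
#'
#' The (unnormalized) empirical Hilbert-Schmidt Independence Criterion
#' `tr(K H L H)` between two kernel matrices over the same samples, with H
#' the centering matrix. It is symmetric and bilinear in its arguments, and
#' nonnegative when both kernels are positive semidefinite. Only relative
#' magnitudes matter in the model objectives, so no `1/(m-1)^2` prefactor
#' is applied.
#'
#' @param K,L square numeric matrices of the same dimension.
#' @return A single number.
#' @export
hsic <- function(K, L) {
  if (!is.matrix(K) || !is.matrix(L) ||
      nrow(K) != ncol(K) || !all(dim(K) == dim(L))) {
    stop("'K' and 'L' must be square matrices of the same dimension")
  }
  # tr(K H L H) = sum((HKH) * t(L)); L symmetric in all uses, but use t()
  # so the identity holds for any L
  sum(center_kernel(K) * t(L))
}
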