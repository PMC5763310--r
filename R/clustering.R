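#' Sum the per-view consensus kernels
#'
#' The clustering input of both models is the elementwise (linear) sum of
#' the per-view reconstructed kernels: `sum C_i` for the enhanced model,
#' `sum K_i` for the consensus model. The sum of unit-trace PSD matrices is
#' PSD with trace equal to the number of views.
#'
#' @param C_list nonempty list of n x n kernels (or an [ecmc()]/[cmc()]
#'   fit, from which the consensus kernels are taken).
#' @return An n x n matrix.
#' @export
combine_consensus <- function(C_list) {
  if (inherits(C_list, "ecmc")) C_list <- C_list$C
  if (inherits(C_list, "cmc")) C_list <- C_list$K
  if (!is.list(C_list) || length(C_list) == 0L) {
    stop("'C_list' must be a nonempty list of kernels")
  }
  n <- nrow(C_list[[1]])
  for (C in C_list) {
    if (!all(dim(C) == n)) stop("kernels in 'C_list' differ in dimension")
  }
  Reduce(`+`, C_list)
}

#' Consensus kernel of a fitted model
#'
#' @param object an [ecmc()] or [cmc()] fit.
#' @param ... unused.
#' @return The summed consensus kernel used for clustering.
#' @export
consensus_kernel <- function(object, ...) UseMethod("consensus_kernel")

#' @rdname consensus_kernel
#' @export
consensus_kernel.ecmc <- function(object, ...) combine_consensus(object$C)

#' @rdname consensus_kernel
#' @export
consensus_kernel.cmc <- function(object, ...) combine_consensus(object$K)

#' Spectral clustering with replicated k-means
#'
#' Embeds the samples with the top-k eigenvectors of (a normalization of)
#' the kernel, normalizes the embedding rows to unit norm, and runs k-means
#' `n_replicates` times from random initializations. All replicate
#' labelings are returned -- downstream evaluation averages the metric over
#' replicates -- together with a consensus labeling, the replicate with the
#' smallest within-cluster sum of squares.
#'
#' Normalization of the kernel before eigendecomposition:
#' \describe{
#'   \item{`"symmetric"`}{the classic normalized spectral clustering
#'     (Ng-Jordan-Weiss): `D^{-1/2} K D^{-1/2}` with `D` the degree
#'     (row-sum) matrix. This presumes a nonnegative affinity; if `K` has
#'     negative entries it is first shifted entrywise by `-min(K)`, and a
#'     small ridge is added if any degree is still near zero.}
#'   \item{`"none"`}{spectral projection of the kernel itself: top-k
#'     eigenvectors of `K`, rows normalized to unit norm. No degree
#'     normalization, which suits the centered, mixed-sign consensus
#'     kernels the models produce, whose row sums are near zero by
#'     construction.}
#'   \item{`"scaled"`}{kernel principal components: top-k eigenvectors
#'     scaled by the square root of their eigenvalues, no row
#'     normalization. Directions carrying little consensus mass are
#'     down-weighted instead of being inflated to equal weight, which
#'     stabilizes k-means when the consensus kernel is effectively of
#'     lower rank than k.}
#'   \item{`"auto"` (default)}{`"symmetric"` when `K` is entrywise
#'     nonnegative (a genuine affinity, e.g. a Gaussian kernel), otherwise
#'     `"scaled"`.}
#' }
#'
#' @param K symmetric kernel/affinity matrix.
#' @param k number of clusters, `1 <= k <= n`.
#' @param n_replicates number of k-means replicates.
#' @param seed integer seed making the replicate stream reproducible;
#'   `NULL` leaves the random-number state alone.
#' @param normalization `"auto"`, `"symmetric"`, `"none"` or `"scaled"`
#'   (see Details).
#' @return An object of class `"spectral_clustering"`: `labels` (consensus
#'   labeling by best within-cluster sum of squares), `embedding` (n x k,
#'   unit-norm rows), `replicate_labels` (n x n_replicates integer matrix),
#'   `k`, `n_replicates`, `seed`, `normalization`.
#' @export
spectral_cluster <- function(K, k, n_replicates = 100, seed = NULL,
                             normalization = c("auto", "symmetric", "none",
                                               "scaled")) {
  normalization <- match.arg(normalization)
  if (!is.matrix(K) || nrow(K) != ncol(K)) stop("'K' must be square")
  n <- nrow(K)
  if (k < 1 || k > n) stop("'k' must be between 1 and n = ", n)
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K)))) {
    stop("'K' must be symmetric")
  }
  K <- (K + t(K)) / 2

  if (normalization == "auto") {
    normalization <- if (min(K) >= 0) "symmetric" else "scaled"
  }
  A <- K
  if (normalization == "symmetric") {
    if (min(A) < 0) A <- A - min(A)      # shift to a nonnegative affinity
    d <- rowSums(A)
    if (any(d < n * 1e-12)) {            # disconnected/degenerate fallback
      A <- A + diag(1e-8, n)
      d <- rowSums(A)
    }
    s <- 1 / sqrt(d)
    A <- A * outer(s, s)
  }
  e <- eigen(A, symmetric = TRUE)
  U <- e$vectors[, seq_len(k), drop = FALSE]
  if (normalization == "scaled") {
    U <- U %*% diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
  } else {
    rn <- sqrt(rowSums(U^2))
    rn[rn < 1e-12] <- 1
    U <- U / rn
  }

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (k == 1L) {
    reps <- matrix(1L, n, n_replicates)
    wss <- rep(0, n_replicates)
  } else if (k == n) {
    reps <- matrix(rep(seq_len(n), n_replicates), n, n_replicates)
    wss <- rep(0, n_replicates)
  } else {
    reps <- matrix(0L, n, n_replicates)
    wss <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      km <- stats::kmeans(U, centers = k, nstart = 1, iter.max = 100)
      reps[, r] <- km$cluster
      wss[r] <- km$tot.withinss
    }
  }
  structure(list(
    labels = reps[, which.min(wss)],
    embedding = U,
    replicate_labels = reps,
    k = k, n_replicates = n_replicates, seed = seed,
    normalization = normalization
  ), class = "spectral_clustering")
}

#' @export
print.spectral_clustering <- function(x, ...) {
  cat(sprintf("spectral clustering: n = %d, k = %d, %d k-means replicates (%s normalization)\n",
              nrow(x$embedding), x$k, x$n_replicates, x$normalization))
  cat("consensus cluster sizes:",
      paste(table(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
labels.spectral_clustering <- function(object, ...) object$labels
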