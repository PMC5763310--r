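#' Normalized mutual information between two partitions
#'
#' Computed from the contingency table `N[C, C*]` of the two labelings as
#' `sum N log(n N / (N_C N_C*)) / sqrt(sum N_C log(N_C/n) * sum N_C* log(N_C*/n))`,
#' with the convention `0 log 0 = 0`. The value is 1 for identical
#' partitions (up to relabeling) and 0 for independent ones. If either
#' partition has a single cluster the denominator vanishes and NMI is
#' defined as 0 (continuity from the independent case).
#'
#' @param pred,truth label vectors of equal length (any atomic type).
#' @return A number in \[0, 1\].
#' @examples
#' nmi(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1: relabeling-invariant
#' nmi(c(1, 1, 2, 2), c(1, 2, 1, 2))  # 0: independent
#' @export
nmi <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("'pred' and 'truth' must have the same length")
  }
  n <- length(pred)
  tab <- table(pred, truth)
  nc <- rowSums(tab)
  nk <- colSums(tab)
  pos <- tab > 0
  num <- sum(tab[pos] * log(n * tab[pos] / outer(nc, nk)[pos]))
  hc <- sum(nc * log(nc / n))
  hk <- sum(nk * log(nk / n))
  if (hc == 0 || hk == 0) return(0)
  val <- num / sqrt(hc * hk)
  # guard against rounding slightly past the theoretical range
  min(max(val, 0), 1)
}

#' Clustering accuracy under the best one-to-one label matching
#'
#' The fraction of samples whose predicted label equals the true label after
#' the predicted cluster labels are remapped by the one-to-one assignment
#' (Hungarian method on the contingency table) that maximizes agreement.
#' When the two labelings use different numbers of clusters the contingency
#' table is padded with zero rows/columns to square.
#'
#' @param pred,truth label vectors of equal length.
#' @return A number in \[0, 1\].
#' @examples
#' clustering_accuracy(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1
#' clustering_accuracy(c(1, 1, 2, 2), c(1, 2, 1, 2))  # 0.5
#' @export
clustering_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("'pred' and 'truth' must have the same length")
  }
  tab <- unclass(table(pred, truth))
  k <- max(dim(tab))
  sq <- matrix(0, k, k)
  sq[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  # Hungarian minimizes; negate to maximize matched mass
  perm <- solve_assignment(-sq)
  sum(sq[cbind(seq_len(k), perm)]) / length(pred)
}

#' Minimum-cost one-to-one assignment (Hungarian method)
#'
#' Solves the linear assignment problem on a square cost matrix by the
#' Jonker-Volgenant shortest augmenting path construction in O(n^3).
#' Used internally for the label matching in [clustering_accuracy()];
#' exported because optimal matching of cluster labels is useful on its own.
#'
#' @param cost square numeric cost matrix.
#' @return An integer vector `p` with `p[i]` the column assigned to row `i`.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  if (ncol(cost) != n) stop("'cost' must be square")
  # arrays indexed 1..n+1; index 1 is the virtual root column
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)        # p[j]: row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0 + 1] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          u[p[j] + 1] <- u[p[j] + 1] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1) break
    }
  }
  out <- integer(n)
  out[p[2:(n + 1)]] <- seq_len(n)
  out
}

#' Mean silhouette score of a clustering
#'
#' For each sample x let `m_x` be its mean Euclidean distance to the other
#' members of its own cluster and `n_x` the smallest mean distance to the
#' members of any other cluster; the per-sample silhouette is
#' `(n_x - m_x) / max(m_x, n_x)` and the score is its mean over samples.
#' Samples in singleton clusters get silhouette 0 (the usual convention).
#' Computed on a coordinate representation -- for this package's own
#' clusterings that is the spectral embedding.
#'
#' @param embedding numeric matrix, samples x coordinates.
#' @param labels cluster labels, one per row of `embedding`; at least two
#'   distinct clusters.
#' @return A number in \[-1, 1\].
#' @export
silhouette_score <- function(embedding, labels) {
  embedding <- as.matrix(embedding)
  if (nrow(embedding) != length(labels)) {
    stop("'labels' must have one entry per row of 'embedding'")
  }
  if (length(unique(labels)) < 2L) {
    stop("silhouette is undefined for a single cluster")
  }
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             dist(embedding))
  mean(sil[, "sil_width"])
}

#' Mean and standard error over replicates
#'
#' @param values numeric vector of per-replicate metric values.
#' @return Named numeric vector `c(mean, se)` with `se = sd/sqrt(R)`;
#'   `se = 0` for a single value.
#' @export
aggregate_replicates <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("'values' must be nonempty")
  se <- if (length(values) == 1L) 0 else stats::sd(values) / sqrt(length(values))
  c(mean = mean(values), se = se)
}

#' Evaluate replicated clusterings against ground truth
#'
#' Computes NMI and accuracy for every k-means replicate of a
#' [spectral_cluster()] result (or any matrix of labelings) against the true
#' labels, and aggregates them as mean and standard error -- the "average
#' clustering result" convention: the metric is averaged over replicates,
#' labels are never averaged.
#'
#' @param x a `spectral_clustering` object or an n x R matrix of replicate
#'   labelings (one column per replicate).
#' @param truth true label vector of length n.
#' @param silhouette_embedding optional samples x coordinates matrix on
#'   which to also compute the mean silhouette of the consensus labeling
#'   (defaults to the spectral embedding when `x` is a
#'   `spectral_clustering` object).
#' @return A list of class `"clustering_evaluation"` with per-replicate
#'   values and `nmi_mean`, `nmi_se`, `acc_mean`, `acc_se`, and
#'   `silhouette` (or `NA` if no embedding is available).
#' @export
evaluate_clustering <- function(x, truth, silhouette_embedding = NULL) {
  if (inherits(x, "spectral_clustering")) {
    reps <- x$replicate_labels
    if (is.null(silhouette_embedding)) silhouette_embedding <- x$embedding
    consensus <- x$labels
  } else {
    reps <- as.matrix(x)
    consensus <- reps[, 1]
  }
  if (nrow(reps) != length(truth)) {
    stop("'truth' must have one label per sample")
  }
  nmi_r <- apply(reps, 2, nmi, truth = truth)
  acc_r <- apply(reps, 2, clustering_accuracy, truth = truth)
  nmi_a <- aggregate_replicates(nmi_r)
  acc_a <- aggregate_replicates(acc_r)
  sil <- if (!is.null(silhouette_embedding) &&
             length(unique(consensus)) > 1L) {
    silhouette_score(silhouette_embedding, consensus)
  } else {
    NA_real_
  }
  structure(list(
    nmi_mean = unname(nmi_a["mean"]), nmi_se = unname(nmi_a["se"]),
    acc_mean = unname(acc_a["mean"]), acc_se = unname(acc_a["se"]),
    silhouette = sil,
    per_replicate = data.frame(replicate = seq_along(nmi_r),
                               nmi = nmi_r, acc = acc_r)
  ), class = "clustering_evaluation")
}

#' @export
print.clustering_evaluation <- function(x, ...) {
  cat(sprintf("NMI %.4f +/- %.4f | ACC %.4f +/- %.4f | silhouette %s | %d replicates\n",
              x$nmi_mean, x$nmi_se, x$acc_mean, x$acc_se,
              ifelse(is.na(x$silhouette), "NA", sprintf("%.4f", x$silhouette)),
              nrow(x$per_replicate)))
  invisible(x)
}
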