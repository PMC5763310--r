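# Two-view Gaussian-mixture simulators with known half/half ground truth.
# Both start from one 2 x n base draw (first n/2 columns from component 1,
# rest from component 2) shared across views, add per-view white noise to
# form the consensus blocks A_i, derive the disagreement blocks B_i, row-
# normalize every block to zero mean / unit Euclidean norm, and stack
# X_i = [A_i; scale * B_i].

draw_mixture <- function(n, mean1, mean2, sd1, sd2) {
  half <- n %/% 2
  cbind(mean1 + sd1 * matrix(stats::rnorm(2 * half), 2, half),
        mean2 + sd2 * matrix(stats::rnorm(2 * half), 2, half))
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  expr
}

new_multiview_sim <- function(views, truth, family, params) {
  structure(list(views = views, truth = truth, family = family,
                 params = params), class = "multiview_sim")
}

#' @export
print.multiview_sim <- function(x, ...) {
  cat(sprintf("simulated two-view dataset ('%s'): %d samples, views %s\n",
              x$family, length(x$truth),
              paste(vapply(x$views, function(v) paste(dim(v), collapse = "x"),
                           character(1)), collapse = " and ")))
  cat("params:", paste(names(x$params),
                       vapply(x$params, format, character(1)),
                       sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Simulate two views with a scaled permuted disagreement block
#'
#' Draws `n` two-dimensional samples from a two-component Gaussian mixture
#' (defaults: means (-4, 3) and (7, -8), diagonal covariance (10, 5); first
#' half of the samples from component 1, second half from component 2) and
#' builds, per view i = 1, 2:
#' * `A_i` = base draw + white noise (sd `noise_sd`): the consensus block,
#'   shared cluster structure across views;
#' * `B_i` = `A_i` with columns randomly permuted (a fresh permutation per
#'   view) + fresh white noise: the disagreement block, whose structure
#'   conflicts between and within views;
#' * each of `A_1, A_2, B_1, B_2` is row-normalized to zero mean and unit
#'   Euclidean norm, then `X_i = rbind(A_i, t * B_i)` (4 x n).
#'
#' The scale `t >= 0` dials the disagreement strength: `t = 0` leaves pure
#' consensus signal; large `t` drowns the shared structure in conflicting
#' similarity, the regime the enhanced model is designed for.
#'
#' @param t nonnegative disagreement scale.
#' @param n even number of samples (half per component).
#' @param seed integer seed; the dataset is a deterministic function of it.
#' @param mean1,mean2 component means (length-2).
#' @param sd1,sd2 per-coordinate standard deviations of the two components
#'   (length-2; diagonal covariance).
#' @param noise_sd standard deviation of the additive white noise.
#' @return A `"multiview_sim"` object: `views` (list of two 4 x n
#'   matrices), `truth` (1 for the first half, 2 for the second), `family`,
#'   `params`.
#' @export
simulate_disagreement <- function(t = 1, n = 100, seed = NULL,
                                  mean1 = c(-4, 3), mean2 = c(7, -8),
                                  sd1 = sqrt(c(10, 5)), sd2 = sqrt(c(10, 5)),
                                  noise_sd = 1) {
  if (t < 0) stop("'t' must be nonnegative")
  if (n %% 2 != 0 || n < 4) stop("'n' must be even and >= 4")
  with_seed(seed, {
    base <- draw_mixture(n, mean1, mean2, sd1, sd2)
    A1 <- base + matrix(stats::rnorm(2 * n, sd = noise_sd), 2, n)
    A2 <- base + matrix(stats::rnorm(2 * n, sd = noise_sd), 2, n)
    B1 <- A1[, sample.int(n)] + matrix(stats::rnorm(2 * n, sd = noise_sd), 2, n)
    B2 <- A2[, sample.int(n)] + matrix(stats::rnorm(2 * n, sd = noise_sd), 2, n)
    X1 <- rbind(normalize_features(A1), t * normalize_features(B1))
    X2 <- rbind(normalize_features(A2), t * normalize_features(B2))
    new_multiview_sim(
      views = list(view1 = X1, view2 = X2),
      truth = rep(1:2, each = n / 2),
      family = "disagreement_scale",
      params = list(t = t, n = n, seed = seed, noise_sd = noise_sd)
    )
  })
}

#' Simulate two views with exchanged samples as disagreement
#'
#' Draws the base mixture (defaults: means (0, 1) and (11, -10), identity
#' covariance) and per-view consensus blocks `A_i` = base + white noise as
#' in [simulate_disagreement()]. The disagreement blocks arise by
#' exchanging `s` samples between the two views' consensus blocks at
#' independently chosen positions: with `idx1`, `idx2` two random size-`s`
#' column sets, `B_1` is `A_1` with columns `idx1` replaced by
#' `A_2[, idx2]`, and `B_2` is `A_2` with columns `idx2` replaced by
#' `A_1[, idx1]`. Because the positions are drawn independently, roughly
#' half of the transplanted columns land on a position of the opposite
#' mixture component, so growing `s` scrambles the cluster structure of the
#' `B` blocks and increases the conflict between (and within) views. All
#' four blocks are then row-normalized and stacked: `X_i = rbind(A_i, B_i)`
#' (no scale factor).
#'
#' @param s number of exchanged samples, `0 <= s <= n/2`.
#' @inheritParams simulate_disagreement
#' @return A `"multiview_sim"` object as in [simulate_disagreement()];
#'   `params` records the exchanged index sets.
#' @export
simulate_exchange <- function(s = 25, n = 100, seed = NULL,
                              mean1 = c(0, 1), mean2 = c(11, -10),
                              sd1 = c(1, 1), sd2 = c(1, 1),
                              noise_sd = 1) {
  if (s < 0 || s > n / 2) stop("'s' must be between 0 and n/2")
  if (n %% 2 != 0 || n < 4) stop("'n' must be even and >= 4")
  s <- as.integer(s)
  with_seed(seed, {
    base <- draw_mixture(n, mean1, mean2, sd1, sd2)
    A1 <- base + matrix(stats::rnorm(2 * n, sd = noise_sd), 2, n)
    A2 <- base + matrix(stats::rnorm(2 * n, sd = noise_sd), 2, n)
    idx1 <- sort(sample.int(n, s))
    idx2 <- sort(sample.int(n, s))
    B1 <- A1
    B2 <- A2
    if (s > 0) {
      B1[, idx1] <- A2[, idx2]
      B2[, idx2] <- A1[, idx1]
    }
    X1 <- rbind(normalize_features(A1), normalize_features(B1))
    X2 <- rbind(normalize_features(A2), normalize_features(B2))
    new_multiview_sim(
      views = list(view1 = X1, view2 = X2),
      truth = rep(1:2, each = n / 2),
      family = "sample_exchange",
      params = list(s = s, n = n, seed = seed, noise_sd = noise_sd,
                    idx1 = idx1, idx2 = idx2)
    )
  })
}

#' Block-structured kernel fixture with known truth
#'
#' A noisy block-constant similarity matrix: `within` on the diagonal
#' blocks, `between` off them, plus symmetric Gaussian noise, projected
#' back onto the PSD cone (negative eigenvalues clipped to zero). Intended
#' as a controlled input for exercising spectral clustering and metrics.
#'
#' @param block_sizes integer vector of cluster sizes.
#' @param within,between similarity inside/between blocks
#'   (`within > between >= 0`).
#' @param noise_sd standard deviation of the symmetric noise.
#' @param seed integer seed.
#' @return A list with `K` (the kernel) and `truth` (block labels).
#' @export
block_kernel_fixture <- function(block_sizes, within = 1, between = 0,
                                 noise_sd = 0, seed = NULL) {
  if (!(within > between && between >= 0)) {
    stop("need within > between >= 0")
  }
  with_seed(seed, {
    truth <- rep(seq_along(block_sizes), block_sizes)
    n <- length(truth)
    K <- matrix(between, n, n)
    K[outer(truth, truth, "==")] <- within
    if (noise_sd > 0) {
      E <- matrix(stats::rnorm(n * n, sd = noise_sd), n, n)
      K <- K + (E + t(E)) / 2
      e <- eigen(K, symmetric = TRUE)
      K <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
      K <- (K + t(K)) / 2
    }
    list(K = K, truth = truth)
  })
}
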