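# Independent reference implementations used as oracles. These deliberately
# take the slow, literal route (explicit centering matrix, double loops,
# exhaustive enumeration) so they share no code path with the package.

rand_sym <- function(n, sd = 1) {
  A <- matrix(rnorm(n * n, sd = sd), n, n)
  (A + t(A)) / 2
}

rand_psd <- function(n, rank = n) {
  B <- matrix(rnorm(n * rank), n, rank)
  tcrossprod(B) / rank
}

# tr(K H L H) via the explicit centering matrix and a double loop
hsic_bruteforce <- function(K, L) {
  n <- nrow(K)
  H <- diag(n) - matrix(1 / n, n, n)
  P <- H %*% K %*% H
  acc <- 0
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      acc <- acc + P[a, b] * L[b, a]
    }
  }
  acc
}

# NMI straight from entropies of the contingency table (base-2 logs,
# normalization makes the base cancel)
nmi_bruteforce <- function(a, b) {
  n <- length(a)
  ua <- unique(a)
  ub <- unique(b)
  mi <- 0
  for (x in ua) {
    for (y in ub) {
      pxy <- sum(a == x & b == y) / n
      if (pxy > 0) {
        mi <- mi + pxy * log2(pxy / ((sum(a == x) / n) * (sum(b == y) / n)))
      }
    }
  }
  ha <- -sum(vapply(ua, function(x) {
    p <- sum(a == x) / n
    p * log2(p)
  }, numeric(1)))
  hb <- -sum(vapply(ub, function(y) {
    p <- sum(b == y) / n
    p * log2(p)
  }, numeric(1)))
  if (ha == 0 || hb == 0) return(0)
  mi / sqrt(ha * hb)
}

# all permutations of 1..k, recursively
all_perms <- function(k) {
  k <- as.integer(k)
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

# accuracy maximized by exhaustive search over label permutations
acc_bruteforce <- function(pred, truth) {
  pf <- as.integer(factor(pred))
  tf <- as.integer(factor(truth))
  k <- max(max(pf), max(tf))
  best <- 0
  for (p in all_perms(k)) {
    best <- max(best, mean(p[pf] == tf))
  }
  best
}

# minimum assignment cost by exhaustive permutation search
assignment_bruteforce <- function(cost) {
  n <- nrow(cost)
  best <- Inf
  for (p in all_perms(n)) {
    best <- min(best, sum(cost[cbind(seq_len(n), unlist(p))]))
  }
  best
}

# ECMC objective evaluated literally with the explicit centering matrix
ecmc_obj_bruteforce <- function(W, C, D, alpha, beta) {
  n <- nrow(W[[1]])
  H <- diag(n) - matrix(1 / n, n, n)
  v <- length(W)
  tr <- function(M) sum(diag(M))
  obj <- 0
  for (i in seq_len(v)) {
    obj <- obj + tr(W[[i]] %*% H %*% (C[[i]] + D[[i]]) %*% H)
  }
  for (i in seq_len(v)) {
    for (j in seq_len(v)) {
      if (i != j) obj <- obj + alpha * tr(C[[i]] %*% H %*% C[[j]] %*% H)
      obj <- obj - beta * tr(C[[i]] %*% H %*% D[[j]] %*% H)
    }
  }
  obj
}

# small deterministic two-view kernel fixture: noisy 2-block structure
two_view_fixture <- function(n = 30, noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  make <- function() {
    f <- block_kernel_fixture(c(n / 2, n / 2), within = 1, between = 0,
                              noise_sd = noise_sd)
    f$K
  }
  list(W = list(make(), make()), truth = rep(1:2, each = n / 2))
}
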