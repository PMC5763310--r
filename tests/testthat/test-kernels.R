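test_that("gaussian kernel matches the closed form and its basic geometry", {
  # 1 feature, 2 samples at 0 and 1, sigma = 1
  X <- matrix(c(0, 1), nrow = 1)
  W <- gaussian_kernel(X, bandwidth = 1)
  expect_equal(W[1, 2], exp(-0.5), tolerance = 1e-12)

  set.seed(1)
  X <- matrix(rnorm(5 * 8), 5, 8)
  X[, 4] <- X[, 2]  # duplicate sample
  W <- gaussian_kernel(X, bandwidth = 0.7)
  expect_equal(diag(W), rep(1, 8))
  expect_equal(W[2, 4], 1)
  expect_equal(W, t(W))
})

test_that("gaussian kernel is PSD on random inputs and median heuristic is used", {
  set.seed(42)
  for (r in 1:5) {
    X <- matrix(rnorm(4 * 12), 4, 12)
    W <- gaussian_kernel(X)
    ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
    expect_equal(attr(W, "bandwidth"), median_bandwidth(X))
  }
})

test_that("gaussian kernel rejects bad input", {
  expect_error(gaussian_kernel(matrix(1, 2, 1)), "at least 2 samples")
  expect_error(gaussian_kernel(matrix(c(1, NA, 2, 3), 2, 2)), "non-finite")
  expect_error(gaussian_kernel(matrix(rnorm(6), 2, 3), bandwidth = 0),
               "positive")
})

test_that("row normalization gives zero mean, unit norm, and is idempotent", {
  expect_equal(normalize_features(matrix(c(1, 2, 3), 1, 3)),
               matrix(c(-1, 0, 1) / sqrt(2), 1, 3), tolerance = 1e-14)

  set.seed(7)
  X <- matrix(rnorm(12), 3, 4)
  N <- normalize_features(X)
  expect_equal(rowMeans(N), rep(0, 3), tolerance = 1e-12)
  expect_equal(rowSums(N^2), rep(1, 3), tolerance = 1e-12)
  expect_equal(normalize_features(N), N, tolerance = 1e-12)
  # column mode is the transposed operation
  expect_equal(normalize_features(t(X), margin = "column"), t(N),
               tolerance = 1e-12)

  X[2, ] <- 5
  expect_error(normalize_features(X), "row\\(s\\) 2")
})

test_that("hsic matches the explicit-H brute force and handles edge kernels", {
  set.seed(11)
  for (r in 1:5) {
    K <- rand_sym(5)
    L <- rand_sym(5)
    expect_equal(hsic(K, L), hsic_bruteforce(K, L), tolerance = 1e-10)
  }
  # constant kernel is annihilated by centering
  n <- 6
  expect_equal(hsic(matrix(1, n, n), rand_sym(n)), 0, tolerance = 1e-12)
  # K = L = I_2: tr(HH) = tr(H) = n - 1 = 1
  expect_equal(hsic(diag(2), diag(2)), 1, tolerance = 1e-12)
  expect_error(hsic(diag(2), diag(3)), "same dimension")
})

test_that("hsic is symmetric, bilinear, and nonnegative on PSD kernels", {
  set.seed(3)
  for (r in 1:10) {
    K1 <- rand_sym(6)
    K2 <- rand_sym(6)
    L <- rand_sym(6)
    expect_equal(hsic(K1, L), hsic(L, K1), tolerance = 1e-10)
    a <- runif(1, -2, 2)
    b <- runif(1, -2, 2)
    expect_equal(hsic(a * K1 + b * K2, L),
                 a * hsic(K1, L) + b * hsic(K2, L), tolerance = 1e-9)
    P <- rand_psd(6)
    expect_gte(hsic(P, P), -1e-12)
  }
})

test_that("centering is idempotent and never materializes H incorrectly", {
  set.seed(5)
  K <- rand_sym(9)
  H <- centering_matrix(9)
  expect_equal(H %*% H, H, tolerance = 1e-12)
  expect_equal(as.numeric(H %*% rep(1, 9)), rep(0, 9), tolerance = 1e-12)
  expect_equal(center_kernel(K), H %*% K %*% H, tolerance = 1e-10)
  expect_equal(center_kernel(center_kernel(K)), center_kernel(K),
               tolerance = 1e-10)
})
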