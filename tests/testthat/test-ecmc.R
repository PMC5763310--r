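test_that("consensus-update matrix M reduces correctly in limiting cases", {
  set.seed(41)
  W1 <- rand_psd(4)
  H <- centering_matrix(4)

  expect_equal(build_M(W1, list(rand_psd(4)), list(rand_psd(4), rand_psd(4)),
                       alpha = 0, beta = 0),
               H %*% W1 %*% H, tolerance = 1e-10)
  # alpha = beta = 1, C_2 = D_1 = D_2 = I/n: the coupling terms cancel
  U <- diag(4) / 4
  expect_equal(build_M(W1, list(U), list(U, U), alpha = 1, beta = 1),
               H %*% W1 %*% H, tolerance = 1e-10)
  # W = I_2: H I H = H
  expect_equal(build_M(diag(2), list(), list(), alpha = 0, beta = 0),
               centering_matrix(2), tolerance = 1e-12)
  expect_error(build_M(W1, list(rand_psd(3)), list(), 1, 1), "dimension")
})

test_that("disagreement-update matrix N reduces correctly in limiting cases", {
  set.seed(43)
  W1 <- rand_psd(5)
  H <- centering_matrix(5)
  expect_equal(build_N(W1, list(rand_psd(5)), beta = 0),
               H %*% W1 %*% H, tolerance = 1e-10)
  # single view, W = 2 C1: N = H C1 H
  C1 <- rand_psd(5)
  C1 <- C1 / sum(diag(C1))
  expect_equal(build_N(2 * C1, list(C1), beta = 1),
               H %*% C1 %*% H, tolerance = 1e-10)
  # strongly negative subproblems are still solvable
  r <- max_trace_psd(build_N(W1, list(diag(5) * 10), beta = 50))
  expect_true(is_unit_trace_psd(r$C_star))
})

test_that("decoupled ECMC returns the top centered eigenprojector for C and D", {
  fx <- two_view_fixture(n = 10, noise_sd = 0.05, seed = 51)
  fit <- ecmc(fx$W, alpha = 0, beta = 0)
  for (i in 1:2) {
    P <- max_trace_psd(center_kernel(fx$W[[i]]))$C_star
    expect_equal(fit$C[[i]], P, tolerance = 1e-8)
    expect_equal(fit$D[[i]], P, tolerance = 1e-8)
  }
})

test_that("every returned block passes the PSD/unit-trace certificate", {
  fx <- two_view_fixture(n = 14, noise_sd = 0.2, seed = 52)
  fit <- ecmc(fx$W, alpha = 10, beta = 10)
  for (i in 1:2) {
    expect_true(is_unit_trace_psd(fit$C[[i]], tol = 1e-7))
    expect_true(is_unit_trace_psd(fit$D[[i]], tol = 1e-7))
  }
})

test_that("objective ascends across block updates once all blocks are feasible", {
  for (seed in 1:5) {
    fx <- two_view_fixture(n = 16, noise_sd = 0.2, seed = 60 + seed)
    fit <- ecmc(fx$W, alpha = 1, beta = 1, track_blocks = TRUE)
    expect_true(fit$converged)
    blk <- fit$block_objective
    # the stated initials are infeasible; ascent is guaranteed from the end
    # of the first outer iteration onward
    vals <- blk$value[-seq_len(2 * fit$v - 1)]
    expect_true(all(diff(vals) >= -1e-9))
    # tracked block objective agrees with the literal explicit-H evaluation
    expect_equal(utils::tail(blk$value, 1),
                 ecmc_obj_bruteforce(fit$W, fit$C, fit$D, 1, 1),
                 tolerance = 1e-8)
  }
})

test_that("objective at convergence is invariant to view order and sample relabeling", {
  fx <- two_view_fixture(n = 12, noise_sd = 0.15, seed = 71)
  f1 <- ecmc(fx$W, alpha = 2, beta = 1)
  f2 <- ecmc(rev(fx$W), alpha = 2, beta = 1)
  expect_equal(utils::tail(f1$objective, 1), utils::tail(f2$objective, 1),
               tolerance = 1e-6)

  # permutation equivariance of the summed consensus kernel
  set.seed(72)
  p <- sample(12)
  Wp <- lapply(fx$W, function(W) W[p, p])
  fp <- ecmc(Wp, alpha = 2, beta = 1)
  expect_equal(consensus_kernel(fp), consensus_kernel(f1)[p, p],
               tolerance = 1e-5)
})

test_that("identical views give identical decompositions at the fixed point", {
  fx <- two_view_fixture(n = 12, noise_sd = 0.1, seed = 81)
  W <- fx$W[[1]]
  fit <- ecmc(list(W, W), alpha = 1, beta = 1, tol = 1e-10, obj_tol = 0)
  expect_true(fit$converged)
  expect_equal(fit$C[[1]], fit$C[[2]], tolerance = 1e-6)
  expect_equal(fit$D[[1]], fit$D[[2]], tolerance = 1e-6)
})

test_that("consensus score worked cases and degenerate input", {
  set.seed(91)
  C <- rand_psd(6)
  C <- C / sum(diag(C))
  # identical parts: numerator is half the denominator
  expect_equal(consensus_score(C, C), 0.5, tolerance = 1e-12)
  expect_equal(consensus_score(C, C, W = rand_psd(6)), 0.5, tolerance = 1e-12)
  # degenerate denominator
  Z <- matrix(1, 3, 3) / 3  # constant kernel: centered to zero
  expect_error(consensus_score(Z, Z), "degenerate")
  expect_error(consensus_score(rand_psd(3), rand_psd(4)), "equal dimension")
})

test_that("out-of-range consensus scores warn instead of clamping", {
  # craft C, D with tr(HWHC) negative: use an indefinite reference
  n <- 4
  v1 <- c(1, -1, 1, -1) / 2
  v2 <- c(1, 1, -1, -1) / 2
  C <- tcrossprod(v1)
  D <- tcrossprod(v2)
  # reference anti-aligned with C but partially aligned with D: the
  # numerator and denominator traces get opposite signs
  W <- -tcrossprod(v1) + 0.5 * tcrossprod(v2)
  expect_warning(s <- consensus_score(C, D, W = W), "outside \\[0, 1\\]")
  expect_true(s < 0 || s > 1)
})

test_that("rank-one optima make the reconstructed-kernel score reading collapse to 1/2", {
  # the analytic degeneracy that motivates the input-kernel default
  fx <- two_view_fixture(n = 10, noise_sd = 0.1, seed = 95)
  fit <- ecmc(fx$W, alpha = 1, beta = 1,
              score_reference = "reconstructed")
  expect_equal(fit$consensus, rep(0.5, 2), tolerance = 1e-6)
})

test_that("grid search finds the trivial single point and honors fixed-alpha grids", {
  fx <- two_view_fixture(n = 10, noise_sd = 0.05, seed = 101)
  g <- ecmc_grid(fx$W, alphas = 1, betas = 1, k = 2, metric = "nmi",
                 truth = fx$truth, n_replicates = 5, seed = 1)
  one <- ecmc(fx$W, alpha = 1, beta = 1)
  expect_equal(nrow(g$table), 1)
  expect_equal(utils::tail(g$best_fit$objective, 1),
               utils::tail(one$objective, 1), tolerance = 1e-9)

  gf <- ecmc_grid(fx$W, alphas = 1e10, betas = c(1e8, 1e9), k = 2,
                  metric = "nmi", truth = fx$truth, n_replicates = 3,
                  seed = 1)
  expect_true(all(gf$table$alpha == 1e10))
  expect_equal(nrow(gf$table), 2)
  expect_error(ecmc_grid(fx$W, alphas = 1, betas = 1, metric = "nmi"),
               "truth")
})
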