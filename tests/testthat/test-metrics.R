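test_that("nmi worked examples and label-permutation invariance", {
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(nmi(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)
  # single-cluster partition: zero entropy convention
  expect_equal(nmi(rep(1, 6), c(1, 1, 2, 2, 3, 3)), 0)
  expect_error(nmi(1:3, 1:4), "same length")
})

test_that("accuracy worked examples and optimal matching", {
  expect_equal(clustering_accuracy(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(clustering_accuracy(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(clustering_accuracy(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0.5)
  # unequal cluster counts: padded matching still optimal
  expect_equal(clustering_accuracy(c(1, 1, 1, 1), c(1, 1, 2, 3)), 0.5)
  expect_error(clustering_accuracy(1:3, 1:4), "same length")
})

test_that("nmi and accuracy agree with brute-force oracles on random labelings", {
  set.seed(99)
  for (r in 1:200) {
    n <- sample(5:50, 1)
    k1 <- sample(2:5, 1)
    k2 <- sample(2:5, 1)
    a <- sample.int(k1, n, replace = TRUE)
    b <- sample.int(k2, n, replace = TRUE)
    expect_equal(nmi(a, b), nmi_bruteforce(a, b), tolerance = 1e-10)
    expect_equal(clustering_accuracy(a, b), acc_bruteforce(a, b),
                 tolerance = 1e-12)
  }
})

test_that("metrics are invariant under relabeling of either argument", {
  set.seed(17)
  for (r in 1:20) {
    n <- 30
    a <- sample.int(4, n, replace = TRUE)
    b <- sample.int(3, n, replace = TRUE)
    pa <- sample.int(4)
    pb <- sample.int(3)
    expect_equal(nmi(pa[a], b), nmi(a, b), tolerance = 1e-12)
    expect_equal(nmi(a, pb[b]), nmi(a, b), tolerance = 1e-12)
    expect_equal(clustering_accuracy(pa[a], b), clustering_accuracy(a, b))
    expect_equal(clustering_accuracy(a, pb[b]), clustering_accuracy(a, b))
  }
})

test_that("accuracy against balanced truth is at least 1/k", {
  set.seed(23)
  for (r in 1:20) {
    k <- sample(2:4, 1)
    n <- k * 10
    truth <- rep(seq_len(k), each = 10)
    pred <- sample.int(k, n, replace = TRUE)
    expect_gte(clustering_accuracy(pred, truth), 1 / k)
  }
})

test_that("the assignment solver reproduces exhaustive minimum costs", {
  set.seed(31)
  for (r in 1:50) {
    n <- sample(2:5, 1)
    cost <- matrix(runif(n * n, -5, 5), n, n)
    p <- solve_assignment(cost)
    expect_equal(sort(p), seq_len(n))  # a permutation
    expect_equal(sum(cost[cbind(seq_len(n), p)]),
                 assignment_bruteforce(cost), tolerance = 1e-12)
  }
})

test_that("silhouette matches a hand-computed configuration", {
  emb <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  labs <- c(1, 1, 2, 2)
  # every point: m = 1, n = (10 + sqrt(101))/2; s = (n - m)/n
  m <- 1
  nn <- (10 + sqrt(101)) / 2
  expect_equal(silhouette_score(emb, labs), (nn - m) / nn, tolerance = 1e-12)
  # swapped labels across tight, distant blobs give negative silhouette
  set.seed(8)
  blob <- rbind(matrix(rnorm(20, 0, .1), 10), matrix(rnorm(20, 5, .1), 10))
  good <- rep(1:2, each = 10)
  expect_gt(silhouette_score(blob, good), 0.9)
  # labels cutting across both blobs: within-cluster spread dwarfs the
  # nearest-other-cluster distance, so the mean silhouette is negative
  expect_lt(silhouette_score(blob, rep(c(1, 2), 10)), 0)
  expect_error(silhouette_score(blob, rep(1, 20)), "single cluster")
})

test_that("replicate aggregation gives mean and standard error", {
  expect_equal(aggregate_replicates(c(0.5, 0.5, 0.5)), c(mean = 0.5, se = 0))
  expect_equal(aggregate_replicates(c(0, 1)),
               c(mean = 0.5, se = sd(c(0, 1)) / sqrt(2)), tolerance = 1e-12)
  expect_equal(aggregate_replicates(0.7), c(mean = 0.7, se = 0))
  expect_error(aggregate_replicates(numeric(0)), "nonempty")
})

test_that("evaluate_clustering averages metrics over replicates", {
  reps <- cbind(c(1, 1, 2, 2), c(1, 2, 1, 2), c(2, 2, 1, 1))
  truth <- c(1, 1, 2, 2)
  ev <- evaluate_clustering(reps, truth)
  expect_equal(ev$nmi_mean, mean(c(1, 0, 1)), tolerance = 1e-12)
  expect_equal(ev$acc_mean, mean(c(1, 0.5, 1)), tolerance = 1e-12)
  expect_equal(nrow(ev$per_replicate), 3)
  expect_error(evaluate_clustering(reps, 1:3), "one label per sample")
})
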