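# Shared protocol for the simulation-study checks: best-over-grid
# replicate-averaged metric of the enhanced model, per seed.
table1_grid <- 10^(-2:10)
table1_norms <- c("symmetric", "none", "scaled")

table1_run <- function(family, value, seeds) {
  out <- matrix(NA_real_, length(seeds), 2,
                dimnames = list(NULL, c("nmi", "acc")))
  for (j in seq_along(seeds)) {
    s <- seeds[j]
    sim <- if (family == "t") {
      simulate_disagreement(t = value, seed = s)
    } else {
      simulate_exchange(s = value, seed = s)
    }
    g <- ecmc_grid(sim, alphas = table1_grid, betas = table1_grid, k = 2,
                   metric = "nmi", truth = sim$truth, n_replicates = 100,
                   seed = s, normalizations = table1_norms, stop_at = 1)
    acc <- mean(apply(g$best_clustering$replicate_labels, 2,
                      clustering_accuracy, truth = sim$truth))
    out[j, ] <- c(g$best_score, acc)
  }
  out
}
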