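# ecmc: consensus multi-view kernel clustering

Patients profiled on several omics platforms — mRNA expression, DNA
methylation, miRNA — yield one similarity kernel per platform over the same
samples. The platforms partly agree about how patients cluster and partly
carry strong platform-specific structure; when the conflict dominates,
clustering any single kernel or a naive fusion of them fails. **ecmc**
reconstructs the kernels before clustering.

Two models are provided. The consensus model (CMC) finds per-view kernels
`K_i` (PSD, unit trace) maximizing

    sum_i tr(W_i H K_i H) + lambda * sum_{i != j} tr(K_i H K_j H)

where `W_i` are the input kernels, `H = I - ee'/n` is the centering matrix,
and `tr(K H L H)` is the empirical HSIC dependence between two kernels. The
enhanced model (ECMC) decomposes each reconstructed kernel into a consensus
part `C_i` and a disagreement part `D_i` and maximizes

    sum_i tr(W_i H (C_i + D_i) H) + alpha * sum_{i != j} tr(C_i H C_j H)
                                  - beta * sum_{i,j} tr(C_i H D_j H)

subject to `C_i, D_i >= 0`, `tr(C_i) = tr(D_i) = 1`. The consensus parts
are pulled into mutual agreement, the disagreement parts are pushed away
from every consensus part, and only the sum `C = sum_i C_i` is clustered —
the conflict is discarded, not averaged in. Optimization is block
coordinate ascent; every block update is an exact trace maximization over
the unit-trace PSD cone (closed form: the top eigenprojector), so the
objective is monotone non-decreasing. Downstream, normalized spectral
clustering with 100 replicated k-means runs turns the summed consensus
kernel into labels, and NMI / accuracy (optimal label matching) /
silhouette quantify the result.

See the vignette (`vignettes/consensus-multiview-clustering.Rmd`) for the
models, the optimizer, the stopping rules, the simulation generators, and
the package's design decisions.

## Worked example

Simulate two conflicting views with a planted two-cluster truth, fit the
enhanced model, cluster the summed consensus kernel, and evaluate:

```r
library(ecmc)

sim <- simulate_disagreement(t = 1.2, seed = 1)   # conflicting views
fit <- ecmc(sim, alpha = 1, beta = 10)
fit
#> Enhanced consensus multi-view clustering (ECMC) fit
#>   2 views, 100 samples | alpha = 1, beta = 10
#>   converged after 23 outer iterations, objective 55.8045
#>   consensus scores: view1 = 0.427, view2 = 0.449

cl <- spectral_cluster(consensus_kernel(fit), k = 2,
                       n_replicates = 100, seed = 1)
evaluate_clustering(cl, sim$truth)
#> NMI 1.0000 +/- 0.0000 | ACC 1.0000 +/- 0.0000 | silhouette 0.7841 | 100 replicates
```

All 100 k-means replicates recover the planted clusters exactly (NMI and
accuracy 1 with zero standard error) even though each view's kernel mixes
the shared structure with a conflicting permuted block — the consensus
scores around 0.44 say that under this level of disagreement under half of
each input kernel's centered signal is consensus, and that part is what
gets clustered. In the strong-disagreement regime (`t = 2`), where
single-view clustering collapses, the conventional powers-of-ten
hyperparameter search is one call:

```r
sim2 <- simulate_disagreement(t = 2, seed = 1)
g <- ecmc_grid(sim2, alphas = 10^(-2:4), betas = 10^(-2:4), k = 2,
               metric = "nmi", truth = sim2$truth, seed = 1, stop_at = 1)
g
#> ECMC grid search: 5 points evaluated, best nmi = 1.0000 at alpha = 0.01, beta = 100 (auto embedding)
evaluate_clustering(g$best_clustering, sim2$truth)
#> NMI 1.0000 +/- 0.0000 | ACC 1.0000 +/- 0.0000 | silhouette 0.7721 | 100 replicates
```

`run_pipeline()` chains simulation/IO, kernels, fitting, clustering and
evaluation into a manifest-stamped run directory; `inst/cli/ecmc-cli.R`
exposes the same stages as shell subcommands.

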