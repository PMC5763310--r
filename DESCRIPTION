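Package: ecmc
Title: Consensus Multi-View Kernel Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-view clustering by kernel reconstruction. Implements the
    consensus multi-view clustering model (CMC) and its enhanced variant
    (ECMC), which decompose each view's kernel into a consensus part shared
    across views and a view-specific disagreement part by maximizing
    Hilbert-Schmidt Independence Criterion (HSIC) agreement under
    positive-semidefinite unit-trace constraints. Includes the alternating
    trace-maximization optimizer with an eigenvalue closed form and an
    interior-point cross-check, normalized spectral clustering with
    replicated k-means, clustering evaluation metrics (normalized mutual
    information, accuracy with optimal label matching, silhouette), and
    two-view Gaussian-mixture simulation generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
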