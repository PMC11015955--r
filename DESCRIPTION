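Package: grmec
Title: Graph-Regularized Multi-View Ensemble Clustering for Single-Cell
    Multi-Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint clustering of single-cell multi-omics data (CITE-seq,
    paired scRNA-seq/scATAC-seq) by graph-regularized multi-view ensemble
    learning. A weighted joint nonnegative matrix factorization extracts a
    consensus low-dimensional cell representation from all omics views while
    a weighted consensus over base clustering results learns a co-cluster
    affinity matrix; two graph-Laplacian couplings tie both to a soft
    cluster-indicator matrix, and the whole objective is minimized by
    multiplicative updates with self-tuned view and base-result weights.
    Includes loaders for dense and Matrix Market count matrices, highly
    variable gene selection, built-in base clusterers, ARI/NMI evaluation,
    Wilcoxon rank-sum marker ranking, and a seeded synthetic multi-omics
    generator with planted cluster structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    graphics,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
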