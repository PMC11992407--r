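Package: dropstab
Title: Stability and Quality of Single-Cell Clustering Under Dropouts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures how increasing dropout sparsity and noise corruption
    degrade the stability (cell-pair co-clustering consistency against an
    uncorrupted baseline, adjusted Rand index) versus the quality (cell-type
    homogeneity, completeness, v-measure) of standard single-cell RNA-seq
    clustering pipelines. Provides a seeded hierarchical gamma-negative-binomial
    count simulator with cell-type tree structure, expression-weighted dropout
    injection calibrated to a target sparsity, binomial read-depth thinning,
    three additive/replacement noise models, the PCA - kNN-graph -
    Leiden/Louvain pipeline plus K-Means and agglomerative clustering with
    silhouette-based cluster-number selection, per-cell-type random-cluster
    nulls, entropy-based quality metrics, and tidy sweep orchestration with
    ggplot2 visualisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    ape,
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
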