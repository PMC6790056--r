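Package: metacellr
Title: Metacell Partitioning of Single-Cell RNA-seq UMI Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Partitions single-cell RNA-seq UMI count matrices into
    metacells: disjoint groups of cells that are statistically equivalent
    to repeated multinomial samples from a single RNA pool. Builds a
    balanced K-nn cell similarity graph from rank-transformed Pearson
    correlations, partitions it with a seeded dense-subgraph algorithm,
    stabilizes the partition by bootstrap co-occurrence consensus, filters
    parametric outliers (including doublets) by regularized fold
    enrichment, and verifies within-metacell homogeneity against a
    multinomial sampling model. Also provides metacell expression
    profiles with log-fold enrichment statistics, cross-validated
    expression-prediction diagnostics, a regularized force-directed 2D
    projection, and a ground-truthed synthetic UMI fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    rhdf5,
    withr
Config/testthat/edition: 3
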