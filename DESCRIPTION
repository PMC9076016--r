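Package: gestclock
Title: Cell-Type-Specific Transcriptomic Clock of Gestational Age from
    Single-Cell PBMC Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and interrogating cell-type-specific
    transcriptomic clocks that predict gestational age from single-cell
    RNA-seq profiles of peripheral blood mononuclear cells. Provides a
    negative-binomial synthetic cohort generator with planted
    age-dependent genes, standard single-cell quality-control filters
    and normalization, control-binned gene-set module scoring with
    stage-wise rank-sum comparisons and threshold-based differential
    expression, a pseudo-cell based LASSO plus random-forest regression
    pipeline with subject-stratified splitting and subject-level
    evaluation, and exact tree-path Shapley attributions for gene
    prioritization across cell types.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    matrixStats,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    glmnet,
    ranger,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
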