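Package: immunotype
Title: Immune-Context Tumor Subtyping from Bulk and Single-Cell Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrative transcriptomic pipeline that stratifies tumor
    cohorts into hot, cold and immunosuppressed immune-context subtypes.
    Provides non-negative matrix factorization (NMF) consensus clustering
    with cophenetic rank selection; mean-signature and single-sample
    rank-based gene-set scores; empirical-Bayes moderated-t differential
    expression with one-vs-both-others subtype signatures; a minimal
    gene-panel classifier selected by a false/true-positive-rate sweep that
    bridges bulk and single-cell cohorts; weighted co-expression module
    detection with module-eigengene trait statistics and hub-gene calling;
    lightweight regulon inference with recovery-curve activity scores and
    hypergeometric transcription-factor prioritization; permutation-based
    ligand-receptor interaction testing; Kaplan-Meier and log-rank survival
    stratification with optimal expression cutoffs; and a seeded synthetic
    cohort generator that plants the statistical structure every stage
    assumes, so the whole pipeline is testable without protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    mclust,
    Rcpp,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
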