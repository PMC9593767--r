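Package: neumod
Title: Stability-Guided Clustering and Metagene Modules for Sepsis Neutrophil Heterogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for dissecting neutrophil heterogeneity in sepsis from
    single-cell RNA-seq: per-cell quality control and normalization,
    graph-based clustering with a subsampled adjusted-Rand-index stability
    scan for resolution selection, one-vs-rest Wilcoxon marker detection,
    functional signature scoring with a two-component Gaussian-mixture
    apoptotic-cell classifier, consensus non-negative matrix factorization
    for metagene module discovery with cophenetic rank selection,
    signature-based deconvolution of bulk transcriptomes by non-negative
    least squares, and the severity-association statistics layer (Pearson,
    Welch/Student, Holm correction, ROC/AUC, interaction logistic
    regression). A synthetic-data generator with full ground truth emulates
    the structure of a sepsis peripheral-blood cohort so every stage is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    FNN,
    irlba,
    pracma,
    cluster,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
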