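Package: cfcnv
Title: Copy-Number Screening of Low-Coverage Cell-Free DNA with a
    Convolutional Attention Classifier
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds genome-wide coverage feature matrices from low-pass
    (about 0.2x) cell-free DNA sequencing depth: non-overlapping genomic
    windows, GC and mappability bias correction, sample quality control,
    row normalization, window pruning and low-rank imputation of dropout
    entries. Classifies samples (case versus control) with a 1D
    convolutional neural network carrying a position-wise self-attention
    layer, trained with Adam on binary cross-entropy, and maps the learned
    attention back to genomic windows to rank discriminative regions.
    Includes evaluation utilities (confusion matrix, ROC/AUC, bootstrap
    confidence intervals, stratified cross-validation), gene annotation of
    top regions with hypergeometric over-representation analysis, and a
    synthetic-cohort simulator with GC bias, dropout and group-specific
    copy-number segments so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
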