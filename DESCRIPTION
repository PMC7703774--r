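Package: doubletscore
Title: Doublet Annotation for Single-Cell RNA-Seq Count Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational annotation of doublets (two cells captured under a
    single barcode) in single-cell RNA-seq count data. Implements
    co-expression based doublet scoring (cxds), which flags barcodes that
    co-express pairs of genes less often co-expressed than expected under a
    binomial null; binary-classification based doublet scoring (bcds), which
    trains gradient-boosted trees to discriminate artificial doublets built
    by summing random cell pairs from real barcodes; and their hybrid
    combination. Ships the evaluation protocol used to benchmark doublet
    callers (AUROC, corrected partial AUC at high specificity,
    Davis-Goadrich AUPRC, top-k calling, library-size stratification,
    heterotypic-doublet enrichment), library-size and detected-gene baseline
    scorers, readers and writers for 10x-style MatrixMarket and dense CSV
    count matrices, and a negative-binomial simulator of multi-cell-type
    data with injected, labeled doublets.
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
    Matrix,
    methods,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
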