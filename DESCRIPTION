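Package: permod
Title: Per-Read RNA Modification Analysis for Nanopore Direct RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for per-read N6-methyladenosine (m6A) analysis of
    nanopore direct RNA sequencing data. Reads and writes per-base signal
    and basecall feature tables, modified-base alignments (SAM/BAM MM/ML
    tags) and bedMethyl site tables; generates seeded synthetic datasets
    with known ground truth; implements a semi-supervised per-k-mer
    labeling pipeline (Kolmogorov-Smirnov k-mer preselection, gradient
    boosting, KNN-kernel label propagation); calls modified sites with
    coverage and stoichiometry thresholds and optimizes per-read
    probability thresholds by the Youden index; and provides
    single-molecule analytics: modification co-occurrence (NSD statistic),
    poly(A) tail length association, exon-boundary distance with a
    random-DRACH control, and per-isoform stoichiometry comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    xgboost,
    randomForest,
    Biostrings,
    BiocGenerics,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
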