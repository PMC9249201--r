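Package: chipimpute
Title: Reference-Based Imputation of Sparse Single-Cell ChIP-seq Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputes missing protein-DNA interaction sites in sparse
    single-cell ChIP-seq profiles by training one random-forest classifier per
    missing genomic bin on a binary reference matrix of bulk ChIP-seq
    experiments sharing the cell's protein target. Includes an interpretable
    single-locus mode that ranks the cell's observed bins by model importance
    with nearest-gene annotation and co-expression validation, a validation
    suite (stratified per-bin cross-validation, down-sampling simulations with
    leave-out ablations, Jaccard-based single-cell specificity, randomization
    baselines, Davies-Bouldin clustering quality), and a fully seeded
    synthetic-reference generator with planted cell-type structure so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
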