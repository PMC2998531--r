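Package: mhc2pred
Title: MHC Class II Peptide Binding Prediction from Positional-Scanning
    Combinatorial Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting peptide binding to MHC class II molecules
    and for benchmarking such predictors. Derives 9 x 20 scoring matrices
    from positional-scanning combinatorial peptide library panels and scores
    peptides by 9-mer core scanning; measures peptide sequence similarity
    (shared 9-mer or >80% ungapped identity) and builds similarity-reduced
    (SR) and singular-peptide (SP) datasets with a deterministic forward
    Hobohm-1 algorithm; runs 5-fold cross-validation with ROC/AUC and
    Spearman rank evaluation, including a paired analysis of how homologous
    peptides in training data affect prediction of unrelated peptides; and
    combines predictors by median percentile rank consensus. A seeded
    synthetic-data generator (ground-truth matrices, affinity datasets with
    controlled homolog structure, library panels) makes every pipeline stage
    testable without external downloads.
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
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
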