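Package: qsarstack
Title: Stacked Ensemble QSAR Classification from SMILES and IC50 Bioactivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A target-agnostic workflow for building stacked-generalization
    QSAR classifiers from raw SMILES/IC50 compound tables. Curates and labels
    bioactivity data (salt stripping, canonicalization, deduplication,
    IC50 thresholding, stratified splitting), assembles nine molecular
    fingerprint families as fixed-width feature blocks (MACCS and a hashed
    path fingerprint computed natively; the PaDEL-Descriptor families via
    validated import), trains a grid-tuned matrix of eight base classifiers
    per descriptor block, derives out-of-fold probabilistic features,
    selects an optimal feature subset by a two-step random-forest-importance
    procedure, and fits a calibrated SVM meta-classifier. Includes a
    six-metric evaluation harness (ACC, BACC, Sn, Sp, MCC, AUC) for
    cross-validation and independent tests, and a synthetic planted-motif
    data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    ChemmineR,
    ChemmineOB,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    mixOmics,
    nnet,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
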