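Package: penomics
Title: Penalized Regression and Selective Inference for High-Dimensional
    Molecular Alterations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for high-dimensional molecular covariates
    (mutation indicators, expression Z-scores) against binary or
    right-censored survival outcomes: optional univariate screening with
    Benjamini-Hochberg false discovery rate control, pathwise penalized
    logistic and Cox regression (ridge, lasso, adaptive lasso) with
    cross-validated tuning, post-selection p-values via polyhedral
    conditioning on the lasso selection event, k-fold cross-validation of
    prediction power (accuracy, sensitivity, specificity, AUC, Harrell's
    C-index), multivariate model reporting with hazard/odds ratios, and a
    seeded synthetic-data generator emulating sparse mutation matrices and
    Z-score expression matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    survival,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
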