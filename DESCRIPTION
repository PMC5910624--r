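Package: metaboflag
Title: Quality Control, Statistics and Feature Selection for Metabolomics Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A composable toolkit for feature-level LC-MS metabolomics data
    built around three tab-separated interchange formats: wide feature tables
    (features in rows, samples in columns), design files (per-sample metadata:
    group, run order, batch) and binary flag files. Provides pre-processing
    (blank feature filtering, threshold flags, normalization and re-scaling,
    log/g-log transforms, imputation), quality-control flagging (retention-time
    stability, run-order regression, Bland-Altman replicate agreement,
    coefficient-of-variation and magnitude-difference flags, standardized
    Euclidean and penalized Mahalanobis sample distances), feature-by-feature
    univariate tests with multiple-testing adjustment, multivariate projections
    and classifiers (PCA, PLS-DA, LDA, random forest, SVM, LASSO/elastic-net
    selection), flag algebra and m/z-retention-time matching utilities, a
    synthetic-data generator for validation, and a command-line entry point
    exposing every tool as a subcommand.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tools,
    stats,
    utils,
    grDevices,
    MASS,
    ggplot2,
    lattice,
    glmnet,
    randomForest,
    e1071,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
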