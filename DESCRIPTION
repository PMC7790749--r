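Package: pathboost
Title: Disease-Specific Pathogenicity Classification of Rare Missense Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating disease-specific classifiers
    of rare missense variant pathogenicity. Provides curation of labelled
    variant feature tables (rarity filtering, clinical-assertion conflict
    rules, stratified train/test splitting), nested cross-validation for
    algorithm selection, an AdaBoost ensemble of depth-limited decision
    trees returning a probability of pathogenicity, a clinically
    thresholded evaluation suite (three-way calls, confusion summaries,
    ROC/PR areas, Brier score, permutation and DeLong comparisons,
    prevalence-adjusted predictive values), cohort-level validation by
    case-control odds-ratio enrichment and Kaplan-Meier / Cox survival
    stratification, and seeded synthetic-data generators so every analysis
    is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    pROC,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    class,
    e1071,
    glmnet,
    nnet,
    optparse,
    ranger,
    rpart,
    testthat (>= 3.0.0),
    vcfR,
    xgboost
Config/testthat/edition: 3
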