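Package: icupretest
Title: Predicting Normal and Abnormal ICU Laboratory Blood Test Results
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying redundancy in intensive care unit (ICU)
    laboratory blood testing. Implements two information-based feature
    families for predicting whether the next laboratory blood test will be
    normal or abnormal: the historical pretest probability (the conditional
    probability of a normal result given the number of immediately preceding
    consecutive normal results of the same test) and conditional-entropy
    encodings of patient vitals, demographics and admission diagnosis.
    Provides a probabilistic Takagi-Sugeno fuzzy classifier with wrapper
    feature selection, admission-grouped cross-validation against logistic
    regression, random forest and gradient boosting baselines, a panel of
    imbalance-aware performance metrics (mean G, index balanced accuracy,
    AUROC, PR-AUC and others), Wilcoxon rank-sum comparison with
    Benjamini-Hochberg correction, and a seeded synthetic ICU electronic
    medical record generator so that the entire pipeline is testable without
    access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
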