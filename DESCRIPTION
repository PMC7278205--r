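Package: stagesel
Title: Supervised Discretization and Joint Gene Selection for Tumor Stage
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Binary early- versus late-stage tumor classification from bulk
    gene-expression profiles. Implements supervised Chi-merge discretization
    with weight-of-evidence (WOE) encoding, a joint gene-selection chain
    (stability-aggregated fast correlation-based filtering, information-value
    screening, pairwise-correlation and variance-inflation-factor redundancy
    elimination, and backward stepwise logistic elimination), and training and
    evaluation of five classifiers with ten-fold cross-validation and held-out
    testing (sensitivity, specificity, accuracy, Matthews correlation
    coefficient, and ROC AUC). A synthetic-cohort generator with planted
    differential, redundant, and noise genes makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    withr,
    e1071,
    nnet,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
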