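Package: reosig
Title: Qualitative Rank-Based Signatures for Case/Control Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovery and evaluation of qualitative diagnostic signatures
    built from within-sample relative expression orderings (REO) of feature
    pairs in case/control expression cohorts. Implements reversal-stable
    pair screening, random-forest importance ranking, SVM recursive feature
    elimination with stratified cross-validation, ordinal clinical-covariate
    encoding, grid-searched classifier training (linear/RBF support vector
    machines and L2-regularised logistic regression), and the matching
    evaluation toolkit (sensitivity, specificity, weighted F1, accuracy,
    ROC AUC, Yates-corrected chi-squared homogeneity tests). A synthetic
    cohort generator with planted reversed pairs and monotone per-sample
    distortions makes the whole cascade testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    glmnet,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
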