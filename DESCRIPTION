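Package: tcmreason
Title: Hybrid Model- and Rule-Based Reasoning for Syndrome Pattern Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnosing traditional Chinese medicine (TCM) syndrome
    patterns from tokenized clinical records in integrative medicine. Implements
    the model-based reasoning (MBR) path, in which word- or document-level
    embeddings of the clinical text feed multiclass classifiers that predict the
    syndrome pattern directly, and the hybrid MBR plus rule-based reasoning
    (MBR+RBR) path, in which multilabel classifiers predict syndrome elements
    that a rule knowledge base combines into a pattern. Ships a synthetic
    tokenized-EMR generator emulating a lung-disease ward corpus (10 syndrome
    patterns, 9 syndrome elements, 8 diseases), six classifier families with
    literature hyperparameters (random forest, gradient boosting, linear SVM,
    k-nearest neighbours, multilayer perceptron, convolutional neural network),
    repeated stratified cross-validation with percentile confidence intervals,
    a paired corpus comparison that measures the value of the modern-medicine
    diagnosis token, and an accuracy-scaling analysis that regresses the
    per-class sample size needed to reach a target accuracy on the number of
    pattern types.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
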