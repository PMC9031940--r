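Package: ictalfs
Title: Feature-Selection Method Evaluation for Ictal EEG Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation pipeline for feature-selection methods in ictal
    versus non-ictal EEG epoch classification. Generates seeded synthetic
    annotated scalp EEG with known discriminative structure, preprocesses it
    (bipolar montage, Butterworth high-pass and notch filtering, 2-second
    epoching with 50 percent ictal overlap, 9:1 class rebalancing, five
    sub-band decomposition), extracts two per-channel per-band feature sets
    (spectral and amplitude statistics, Hjorth parameters, sample entropy),
    prunes correlated features, ranks features with six importance methods
    (decision-tree Gini importance, linear-SVM weights, LIME surrogates,
    kernel SHAP, random-forest permutation importance, reciprocal rank
    fusion), evaluates rankings by stepwise feature elimination under 5x2
    cross-validation with the 5x2cv F-test, and quantifies feature-set
    agreement with the Jaccard index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    e1071,
    jsonlite,
    nnet,
    randomForest,
    Rcpp,
    rlang,
    rpart,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
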