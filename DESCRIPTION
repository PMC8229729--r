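Package: kesvr
Title: Ensemble Support Vector Regression for Drug Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug sensitivity (area under the dose-response curve)
    of cancer cell lines from gene expression with a k-means ensemble of
    support vector regressions (kESVR). A global RBF-kernel SVR is fitted on
    target-gene expression, its residuals are clustered by k-means in the
    (response, error) plane, one local SVR is trained per cluster, and the
    per-cluster candidate predictions are arbitrated by a neighbourhood-
    averaged Spearman-correlation score in a PCA-reduced plane. The cluster
    count k and neighbourhood radius r are chosen from the data by minimising
    the average training plus testing mean squared error. Includes a seeded
    synthetic-data generator with planted response regimes, evaluation
    utilities (MSE, R squared, k-fold cross-validation), linear and plain-SVR
    baselines, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
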