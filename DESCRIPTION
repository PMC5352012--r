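Package: roinet
Title: Sparse Linear Models of Multiregional Integration in Resting-State
    fMRI Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the activity of each brain region of interest (ROI) as a
    sparse weighted sum of the activities of other ROIs, using recursive
    feature elimination with a validation-error stopping rule, Lasso and
    elastic-net regularization paths, and single-best-predictor baselines.
    Quantifies how strongly a region's activity depends on the joint
    contribution of several regions via the multiregional prediction gain
    statistic, assesses significance with weight-permutation null models and
    paired t-tests, and aggregates fitted models across subjects into
    group-level integration networks of key predictor regions. Includes a
    synthetic multivariate time-series generator with known ground-truth
    dependency structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
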