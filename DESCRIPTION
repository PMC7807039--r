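Package: rocharvest
Title: Harvest Classifier Performance Indices from a Binormal Mixture
    Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Label-free evaluation of a continuous classifier. The
    population frequency distribution of the log-transformed classifier
    variable is decomposed into two class-conditional Gaussian components
    (the binormal model) by bounded Levenberg-Marquardt least squares on
    a Freedman-Diaconis relative-frequency histogram, optionally with an
    age-stratified two-pass strategy that anchors the positive component
    in a high-prevalence stratum. Every standard diagnostic-test
    performance index is then derived analytically from the fitted
    components: sensitivity, specificity, the binormal ROC curve and its
    area, the optimal cut-off (Youden or misclassification-cost
    criterion), predictive values, likelihood ratios (positive, negative,
    interval and point), disease prevalence, and the reference interval
    of the negative class. A synthetic-cohort generator with known labels
    provides the gold-standard oracle for validating the label-free
    estimates.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
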