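Package: thermobreast
Title: Statistical and Texture Feature Classification of Breast Thermograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Characterises radiometric breast thermograms with a compact set of
    statistical and gray-level co-occurrence (GLCM) texture descriptors computed
    over masked per-breast regions of interest, selects the informative
    descriptors with a Welch two-sample t-test, and benchmarks four classical
    classifiers (linear and quadratic SVM, logistic regression, coarse decision
    tree) under stratified k-fold cross-validation. Classifier performance is
    validated with percentile-bootstrap confidence intervals and exact McNemar
    paired comparisons. A synthetic thermal-cohort generator emulating bilateral
    temperature fields with tumour-like hotspots and vessel structures makes the
    full pipeline reproducible without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
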