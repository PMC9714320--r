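Package: RadioLink
Title: Radiogenomic Association and Prediction Pipeline
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A configurable radiogenomic analysis engine that associates
    tumor imaging (radiomic) features with omics features. It performs
    correlation filtering with multiple-testing control, trains linear,
    regularized (lasso / elastic net, single- and multi-task) and decision
    tree regression models mapping one feature set onto the other,
    evaluates predictions per label with the RMSE-to-standard-deviation
    ratio and its R-squared identity, sweeps decision thresholds to obtain
    AUC curves, establishes significance via refitting permutation tests,
    and emits a structured HTML report plus machine-readable result files.
    Includes a synthetic paired-data generator with planted linear signal
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    glmnet,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    pheatmap,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
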