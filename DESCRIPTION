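Package: gleasonmil
Title: Weakly Supervised Two-Stage Gleason Grade-Group Prediction at Desk Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage, weakly supervised pipeline that predicts ISUP grade
    groups for prostate biopsy slide images from slide-level labels only. A
    patch-level cancer detector is trained by max-pooling multiple-instance
    learning; its penultimate-layer features are assembled into a spatial
    feature map that a residual convolutional classifier maps to one of six
    grade groups. Includes a procedural synthetic-histology generator with
    controlled Gleason-pattern composition, the Gleason score and grade-group
    rule engine (1% noise floor, 5% secondary rule, worst-pattern rule),
    evaluation statistics (ROC/PR AUC, best-F1 operating point, Cohen's kappa
    with and without quadratic weighting, confidence intervals), and the
    mechanism analyses: t-SNE separability of pattern features and the
    ratio-controlled slide-concatenation proportion-sensitivity experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    EBImage,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
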