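Package: edcrowd
Title: Image-Based Crowdedness Measurement for Emergency Departments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring and analysing crowdedness in hospital
    waiting areas from surveillance imagery and visit records. Provides a
    synthetic scene and visit-record generator for fully reproducible
    pipelines, Gaussian-kernel density-map ground truth for head-annotated
    images, a multi-fusion encoder-decoder convolutional network that
    regresses density maps and people counts, counting-accuracy metrics
    (mean counting error and root mean squared error), the half-hourly
    surveillance frame-sampling design with per-slot count aggregation,
    a proxemics-based unit congestion rate built on Hall's 1.2 m personal
    distance, and post-hoc visit-time statistics (diagnosis time and
    post-diagnosis time) with automatic t-test/ANOVA/Kruskal-Wallis
    selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    jsonlite,
    yaml,
    png,
    tiff,
    car
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
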