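Package: spicevision
Title: Visible-Imaging Detection of Adulterant Levels in Powdered Spices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible machine-vision pipeline for detecting mineral
    adulterants (sea foam / meerschaum) in powdered spices such as black and
    red pepper from ordinary RGB photographs. Provides a seedable synthetic
    powder-image generator for five adulteration levels, decomposition of an
    image into 19 colour channels (RGB, CIELAB, HSV, normalised rgb, CrCgCb,
    Ohta I1I2I3 and gray), extraction of 266 first-order and co-occurrence
    texture features per image, sequential forward feature selection under a
    cross-validated residual-sum-of-squares criterion, a hidden-layer-size
    sweep of tanh-sigmoid neural networks and a one-vs-one Gaussian-kernel
    support vector machine, and a confusion-matrix metric suite (per-class,
    macro and micro accuracy, precision, sensitivity and specificity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
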