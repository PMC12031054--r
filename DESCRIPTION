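Package: leafspad
Title: Leaf Chlorophyll (SPAD) Estimation from RGB Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates leaf chlorophyll content (SPAD units) from photographs of
    single leaves on a bright background. Provides HSV-threshold leaf
    segmentation with largest-contour region-of-interest extraction, a panel of
    28 RGB and normalized-rgb color indices, Pearson-correlation feature
    selection and principal-component reduction, and five regression models
    (epsilon-insensitive support vector regression, relevance vector machine,
    a small 1-D convolutional network, and CNN-SVR / CNN-RVM hybrids) under a
    uniform fit/predict contract, with 80/20 split and k-fold cross-validated
    evaluation. A seeded synthetic leaf-image generator with known ground truth
    makes the whole pipeline testable end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    png,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
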