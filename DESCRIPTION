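Package: mcwscreen
Title: Mandibular Cortical Width Measurement and SVM Screening for Low
    Bone Mineral Density
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the width of the inferior mandibular cortex
    continuously on regions of dental panoramic radiographs and classifies
    subjects as low versus normal bone mineral density with a radial basis
    function support vector machine. The measurement pipeline enhances the
    region of interest (histogram equalization, between-class-variance
    thresholding, background removal, high-pass filtering), extracts the
    cortical medial axis with a chessboard distance transform and a
    dynamic-programming ridge trace, reconstructs the cortical margins as a
    disc envelope, and measures width perpendicular to a fitted
    second-order polynomial. A synthetic cortical-ribbon generator with
    exact ground truth supports testing and calibration without clinical
    images, and screening metrics (sensitivity, specificity, predictive
    values, likelihood ratio) are reported with 95 percent confidence
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    withr
Suggests:
    e1071,
    kernlab,
    optparse,
    purrr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
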