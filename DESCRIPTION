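Package: msrp
Title: Multi-Scale Signed Recurrence Plots for Time Series Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes univariate time series as multi-scale signed recurrence
    plot (MS-RP) images and classifies them with 2D fully convolutional
    networks, so that time-series classification is performed as image
    classification. Provides delay embedding and unthresholded recurrence
    matrices under several norms, sign masks that disambiguate rising from
    falling trends, asymmetric recurrence images for very long sequences,
    bilinear multi-scale resizing with validation-based scale selection,
    compact FCN/ResNet/CNN classifiers trained with Adam, UCR-style file
    input and output, seeded synthetic benchmark generators, and the usual
    benchmark comparison metrics (win counts, arithmetic and geometric mean
    ranks, mean per-class error).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
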