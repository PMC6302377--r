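Package: histosparse
Title: Convolutional Sparse Coding of Histopathology Tiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised convolutional sparse coding for tumor/non-tumor
    discrimination from histopathology slide images. Extracts densely
    staining regions of interest from slides by Otsu binarization and
    FFT-based window density, learns an overcomplete dictionary of
    convolutional feature kernels by alternating Locally Competitive
    Algorithm (LCA) inference with Hebbian stochastic gradient updates,
    pools the resulting sparse feature maps into fixed-length descriptors,
    and classifies them with a linear support vector machine or a
    one-hidden-layer multilayer perceptron. Includes a synthetic
    stain-texture image generator for end-to-end testing without
    whole-slide data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    e1071,
    png,
    tibble,
    dplyr,
    purrr,
    tidyr,
    ggplot2,
    generics,
    rlang,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
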