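Package: seedspec
Title: Seed Variety Identification from Near-Infrared Hyperspectral Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pipeline for identifying crop-seed varieties from line-scan
    near-infrared hyperspectral images. Covers reflectance calibration against
    white/dark references, per-seed segmentation by single-band thresholding and
    connected-component labeling, pixel-level spectral preprocessing (Daubechies-6
    wavelet denoising, area normalization, 7-point moving-average smoothing), a
    compact one-dimensional convolutional neural network trained on pixel or
    per-seed average spectra, and a majority-vote decision stage that aggregates
    pixel predictions into per-seed variety calls and pseudo-color prediction
    maps. A synthetic scene generator with a closed-form Bayes-optimal pixel
    accuracy makes every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse,
    jsonlite
Config/testthat/edition: 3
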