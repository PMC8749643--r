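Package: oxispec
Title: Multi-Wavelength Spectral Pulse Oximetry with a 1D Convolutional Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates peripheral oxygen saturation (SpO2) from multi-channel
    transmission spectra. Provides a Beer-Lambert simulator of finger-clip
    spectra over twelve sensor channels (450-860 nm), per-curve min-max
    normalization and uniform-noise data augmentation, a small one-dimensional
    convolutional classifier over ten SpO2 labels (81-99 percent, step 2) with
    weighted-label expectation decoding, exhaustive grid search and Bayesian
    hyperparameter optimization, the classical dual-wavelength ratio-of-ratios
    baseline, a region-by-noise ablation harness, and median/moving-average
    filtering for dynamic time-series measurement.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
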