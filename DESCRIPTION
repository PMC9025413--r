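Package: treebands
Title: Data-Driven Frequency-Band Discovery for Power Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Discovers optimal frequency bands from a power spectrum in a
    self-supervised way. A leaf-count-constrained regression tree is grown
    greedily on (frequency, log power spectral density) to obtain contiguous
    ("member-adjacent") frequency bands for every candidate band count, and an
    AIC-inspired quality score, QS = -ln(r^2) + 2k/N, selects the band count
    automatically. Includes Welch spectral estimation, an exact
    dynamic-programming segmentation oracle, evaluation of fixed named band
    sets (delta/theta/alpha/beta) against a spectrum, a synthetic 1/f spectrum
    and EEG-like signal generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    rpart,
    optparse,
    edfReader
Config/testthat/edition: 3
RoxygenNote: 7.3.3
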