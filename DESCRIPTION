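Package: stalknirs
Title: Near-Infrared Spectroscopy Calibration of Stalk Mechanical Strength
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric calibration pipeline for predicting stalk mechanical
    strength traits (rind penetrometer resistance and breaking force) from
    near-infrared spectra. Provides wide-format spectra input/output, the
    standard scatter-correction and derivative pretreatments (constant offset
    elimination, straight-line subtraction, standard normal variate, min-max
    normalization, multiplicative scatter correction, Savitzky-Golay first and
    second derivatives and their combinations), principal-component
    characterization with GH (Mahalanobis) outlier screening, NIPALS partial
    least squares regression with segmented cross-validation, rank selection,
    pretreatment-by-window model search, external validation and RPD scoring,
    laboratory replicate reduction and trait summaries, and a synthetic
    spectra/reference generator for fully reproducible desk-scale testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
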