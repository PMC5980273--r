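Package: anthospec
Title: Hyperspectral Calibration of Foliar Anthocyanin Content
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Workflow for calibrating leaf anthocyanin content against
    hyperspectral reflectance. Provides the eight spectral transforms used
    in derivative spectroscopy screening (reflectance, reciprocal, base-10
    logarithm, reciprocal logarithm, and their first-order differentials),
    per-wavelength Pearson correlation screening with sensitive-band
    selection, fitting and selection among five single-band calibration
    families (linear, quadratic, power, exponential, logarithmic),
    train/validation evaluation by determination coefficient and RMSE with
    low-content stratification, the pH-differential computation of total
    monomeric anthocyanin as cyanidin 3-glucoside equivalents, and a
    seeded simulator of purple-leaf reflectance spectra for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
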