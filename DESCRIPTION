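Package: ctai
Title: Calibration Transfer by Affine Invariance for NIR Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Transfers multivariate near-infrared calibration models between
    spectrometers without transfer standards. A bespoke PLS1 core is fitted on
    the master instrument; per-latent-variable linear relations between
    min-max normalized scores and predictions are compared across instruments,
    and slave predictions are corrected by a rotation/translation (affine)
    map. Includes the classical comparison methods slope/bias correction,
    multiplicative scatter correction transfer and piecewise direct
    standardization, Kennard-Stone sample selection, paired evaluation
    statistics, and a synthetic paired-instrument spectra generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
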