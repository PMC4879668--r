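Package: sdrslut
Title: Lookup-Table Inverse Modeling for Sub-Diffuse Reflectance Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for sub-diffuse reflectance spectroscopy (sDRS) at short
    source-detector separations: construction of empirical two-dimensional
    lookup tables (LUT) mapping reduced scattering and absorption coefficients
    to absolute reflectance and to sampling depth, LUT-based inverse fitting of
    reflectance spectra to recover scattering power-law parameters, hemoglobin
    concentration and oxygen saturation, Mie-theory forward models for
    polystyrene microsphere calibration phantoms, a 50%-photon translation-curve
    estimator of sampling depth, and a documented synthetic instrument
    surrogate that generates calibration, validation, layered-phantom and
    cohort spectra so the full calibration/validation study can be run without
    the physical probe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    interp,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
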