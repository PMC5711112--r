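Package: filmdose
Title: Radiochromic Film Dosimetry for Image-Guidance Dose Measurement
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reference radiochromic film dosimetry toolchain for measuring
    doses delivered by image-guided radiotherapy (IGRT) imaging systems.
    Reads paired before/after flatbed scans of GAFCHROMIC XRQA2 and EBT3
    film pieces, extracts red-channel region-of-interest statistics,
    converts them to net reflectance change or net optical density change,
    fits rational-function dose-response calibrations in both the general
    three-parameter and the improved zero-intercept form, inverts responses
    to dose with closed-form expressions, propagates response noise and
    calibration-parameter covariance into one-sigma dose uncertainty
    budgets, converts air kerma in air to dose to water via water-to-air
    mass-energy-absorption-coefficient ratios, and assembles surface-dose
    tables and 1D dose profiles. A seeded forward-model generator produces
    synthetic calibration sets, scan pairs, and humanoid-phantom dose
    fixtures so the entire pipeline is testable without physical films.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    tiff,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
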