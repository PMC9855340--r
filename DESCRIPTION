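Package: brachycheck
Title: Independent TG-43 Dose Verification for HDR Brachytherapy Plans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Independent second-check dose calculation for high-dose-rate
    (HDR) brachytherapy plans using the AAPM TG-43U1 2D line-source
    formalism. Evaluates the line-source geometry function, an analytic
    radial dose function and an analytic 2D anisotropy function (fitted
    forms rather than table interpolation), decays the air-kerma strength
    to the treatment day, sums dwell contributions at named verification
    points, and judges the relative dose difference against the treatment
    planning system dose with an error-propagated acceptance band. Reads
    DICOM RT Plan brachytherapy files and a portable plain-text plan
    dialect, and generates synthetic fixture plans.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
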