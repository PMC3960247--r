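Package: colonyquant
Title: Quantification of Colony Formation Assays from Scanned Well Plates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies clonogenic (colony formation) assays from flatbed
    scanner images of 6-, 12- and 24-well plates. Wells are located from a
    rectangular selection and the plate geometry, concentrically cropped, and
    background-thresholded per well via the derivative structure of the
    colony-area-versus-threshold curve, with a cross-well consistency check.
    Colony growth is reported as the percentage of well area covered by
    stained colonies and as an intensity-weighted coverage percentage.
    Dose-response data are fitted with the four-parameter log-logistic model
    to estimate IC50 values. A synthetic plate generator with per-well ground
    truth supports validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    minpack.lm,
    png,
    stats,
    tiff,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
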