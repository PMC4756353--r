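Package: tmquant
Title: Quantitative Two-Photon Image Analysis of the Trabecular Meshwork
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying F-actin density and three-dimensional
    distribution, structural extracellular-matrix pore morphometry,
    autofluorescence intensity, and cell viability in calibrated
    multi-channel two-photon z-stacks of human trabecular meshwork.
    Includes a synthetic tissue-stack generator with full ground truth
    (autofluorescent beam lattices, cortical versus aggregated actin,
    ellipsoidal nuclei, photon-counting noise) so every analysis stage
    can be validated without donor-tissue images, plus paired
    log-transformed t-tests and two-proportion z-tests for
    control/treated comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
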