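Package: osteodisc
Title: Direct-Controlled Calibration of Annulus Fibrosus Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterisation and inverse calibration of intervertebral disc
    mechanics from opening-angle, single-lamella and osteodisc compression
    data. Computes annulus fibrosus hoop (pre-)strain from radially cut disc
    openings, extracts a functional extrafibrillar-matrix modulus over the
    physiological strain range, and calibrates the exponential fibre
    parameters of a Gasser-Ogden-Holzapfel annulus model against axial
    compression force-displacement curves through a reduced-order
    axisymmetric finite-deformation model of the osteodisc. Includes
    continuous tri-linear stiffness characterisation, Lin's concordance
    correlation for agreement assessment, nucleus and geometry sensitivity
    studies, and seeded synthetic-cohort generators so the whole pipeline is
    exercisable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    graphics,
    withr,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
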