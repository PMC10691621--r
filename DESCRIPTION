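Package: artpredict
Title: Predicting Adaptive Re-Planning Need from Head-and-Neck VMAT Plan
    Geometry and Dosimetry
Version: 0.1.0
Authors@R:
    person("artpredict", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pre-treatment prediction of severe radiation mucositis requiring
    adaptive re-planning (ART) in head-and-neck volumetric modulated arc
    therapy (VMAT). Parses DICOM RT Plan, RT Structure Set and RT Dose
    objects, resamples VMAT arcs into 4-degree segments, computes irregular
    MLC aperture areas and equivalent-square field (EQIF) sizes, accumulates
    per-segment dose into 11 EQIF bins, and assembles per-patient
    five-dimensional feature lists (EQIF size, bin dose, CTV-high volume per
    unit BMI, total monitor units, mean oral-cavity dose). Classifies the
    lists with an RBF-kernel support vector machine and a k-nearest-neighbor
    classifier over a test-size by random-seed accuracy sweep, reproduces the
    cohort group statistics (Welch t, two-sample z, per-bin dose comparison),
    and ships a calibrated synthetic-cohort and synthetic-DICOM generator so
    the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
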