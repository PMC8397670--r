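Package: sbrtbench
Title: Benchmarking of Lung SBRT Dose Distributions Prescribed to the Mean ITV Dose
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-institutional quality assurance of stereotactic
    body radiotherapy (SBRT) treatment plans for peripheral lung lesions.
    Normalizes voxelized dose distributions to the mean internal target
    volume (ITV) dose, computes cumulative dose-volume histograms and point
    metrics (Dx%, Vd, dose to the hottest 0.1 ml), RTOG and Paddick
    conformity indices, the gradient index and linear-quadratic biologically
    effective dose, classifies plans against a tiered objective protocol
    with minor-deviation tolerances, and compares plan cohorts across
    delivery techniques and dose-calculation algorithms with a tie-corrected
    Kruskal-Wallis test under a selective multiplicity policy. Ships a
    synthetic plan generator emulating two peripheral-lesion phantom
    patients so that the whole pipeline is testable without clinical data,
    plus DICOM RT Dose / RT Structure Set ingestion and a simple
    single-file plan container.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite,
    mgcv
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
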