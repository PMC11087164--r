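Package: arcqa
Title: Virtual Cylindrical Diode-Array Phantom Toolkit for MR-Linac QA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a virtual model of a cylindrical 1386-diode helical QA
    phantom (ArcCHECK-MR class) for patient-specific quality assurance on a
    1.5 T MR-linac. Generates the detector helix and its unfolded chart
    coordinates, a five-ring pseudo-CT phantom with relative electron density
    (RED) overrides and QA-platform objects, and serializes them as DICOM CT,
    RT Structure Set and RT Dose objects. Implements exit/entrance dose ratio
    (EEDR) calibration, monitor-unit rescaling, local/global distance-to-
    agreement and gamma-index analysis, and an iterative RED tuning loop,
    exercised end to end by a deterministic ray-trace dose engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
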