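Package: hramsst
Title: High-Resolution Accurate Mass System Suitability Testing for LC-HRMS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for running and tracking a high-resolution accurate mass
    system suitability test (HRAM-SST) on LC-HRMS instruments such as
    Orbitraps. Computes theoretical adduct m/z values for a reference-compound
    panel from elemental formulas, extracts apex m/z values from centroided
    mzML runs, scores ppm mass errors against a 3 ppm threshold and a
    bias-randomness criterion, and models long-term mass-accuracy drift and
    calibration-quality effects from a longitudinal history of SST records.
    Includes synthetic-data generators for centroided runs and SST histories
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    mzR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
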