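Package: cadeval
Title: Evaluation of Lesion-Localization CAD Systems Against Multi-Reader Ground Truth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for evaluating computer-aided detection (CAD) of lung
    nodules on chest CT against ground truth consolidated from multiple
    radiologist readers. Merges per-reader annotations into consensus
    nodules by a centre-distance rule, grades them by reader agreement,
    classifies CAD marks as lesion-localizing or false positives using a
    radius-multiple hit criterion, and computes scan-level ROC/AUC with
    DeLong confidence intervals and paired tests between two imaging
    conditions, free-response ROC (FROC) curves with the competition
    performance metric (CPM), and 6 mm size-subgroup analyses. Includes a
    seeded synthetic cohort generator emulating multi-reader annotation and
    two-condition detector output so the full pipeline can be exercised and
    calibrated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
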