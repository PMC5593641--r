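Package: epiclass
Title: Probabilistic Cell-by-Cell Classification of Prostate Tissue from
    Nuclear Biomarker Intensities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a cell-by-cell probabilistic classification workflow
    for prostate tissue built on per-nucleus immunofluorescence intensities of
    an epigenetic marker panel (DAPI, AMACR, 5mC, 5hmC). Provides a synthetic
    log-normal cohort generator, compartment-stratified principal component
    exploration, logistic cancer/normal cell scoring with delta-method
    odds-ratio reporting, cutoff-scan optimization and ROC discrimination
    banding, Mahalanobis k-nearest-neighbor staging and grading, and
    fuzzy-logic aggregation of cell calls into specimen-level tissue
    diagnoses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    readr,
    withr,
    optparse
Config/testthat/edition: 3
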