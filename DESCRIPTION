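Package: wsirisk
Title: Risk Stratification of Breast Tumours from Preoperative Biopsy Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for patient-level risk
    stratification from haematoxylin-and-eosin (H&E) whole-slide images of
    preoperative breast core-needle biopsies. Implements HSV-rule tissue
    segmentation with a capped Otsu saturation threshold, overlapping tile
    extraction with Laplacian-variance blur quality control, Macenko stain
    normalisation with per-slide stain vectors, a pluggable tile-scorer
    contract with ensemble averaging (including a desk-scale reference
    convolutional classifier), upper-percentile patient-level score
    aggregation, Youden-index threshold calibration, agreement statistics
    (Cohen's kappa, sensitivity/specificity, percent agreement, ROC/AUC with
    DeLong intervals), and recurrence-free-survival analysis with
    Kaplan-Meier curves and age-adjusted Cox models. Ships a seeded
    synthetic-cohort generator producing H&E-like slides and linked clinical
    tables so every stage is exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    pROC,
    survival,
    EBImage,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
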