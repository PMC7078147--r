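Package: lesiondyn
Title: Lesion-Level Tumor Heterogeneity from Cross-Correlation of
    Individual Lesion Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies within-patient tumor heterogeneity from the size
    dynamics of individual target lesions in oncology trials. Lesions are
    classified into organ classes by keyword rules, the similarity of every
    within-patient lesion (or organ-aggregate) pair is measured as a lagged
    cross-correlation coefficient, coefficients are grouped by 1-D K-means
    with elbow-based model selection, and a per-patient median
    cross-correlation is carried into Kaplan-Meier, log-rank and Cox
    proportional-hazards analyses of overall survival. Ships a synthetic
    multi-lesion metastatic colorectal cancer trial simulator so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
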