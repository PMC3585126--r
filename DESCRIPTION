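Package: lipidscreen
Title: Cell-Based RNAi Screening Analysis for Cellular Cholesterol Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-content siRNA screens of LDL uptake
    and free cellular cholesterol. Provides per-cell image quantification
    (nuclear segmentation, cell-region approximation, structure detection by
    local adaptive thresholding, extraction of seven phenotypic parameters),
    control-anchored deviation-value scoring with plate-region normalization,
    effector-siRNA and two-siRNA hit-gene calling, multiparametric phenotypic
    fingerprints with functional-group classification and locus-level
    aggregation, secondary-assay decision rules (enzymatic cholesterol,
    delta-delta-CT qPCR, Western densitometry, GFP-overexpression), and a
    seeded synthetic-data generator producing plate layouts, per-cell
    populations, rendered multi-channel images, and secondary-assay tables
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    data.table,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
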