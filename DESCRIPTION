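Package: slidediag
Title: Patch-Level Labeling, Ensembled Probability Maps and Abstaining
    Scan-Level Diagnosis for Whole-Slide Prostate Histopathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning annotated whole-slide images (WSI) of
    prostate tissue into patch-level training data and scan-level
    diagnoses. Implements hierarchical Gleason-grade patch labeling
    across a 40x/20x/10x/5x magnification pyramid (stride-128 patch
    grids, exact polygon-coverage computation, most-severe label
    merging), valid-tissue segmentation (Otsu or a small fully
    convolutional network), a pluggable patch-classifier interface
    producing per-scan probability maps, multi-model and
    multi-magnification map ensembling with spatial median filtering,
    an abstaining scan-level diagnosis rule driven by the cancerous
    tissue percentage with threshold trade-off sweeps, and Spearman
    inter-rater agreement analysis. A synthetic-data module generates
    annotated scans, probability maps and diagnosis cohorts so the
    full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
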