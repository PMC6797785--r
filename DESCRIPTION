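Package: rushscreen
Title: High-Content Screening Analysis for RUSH Secretory-Trafficking Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for high-content phenotypic screens of
    ER-to-Golgi cargo trafficking in the RUSH (retention using selective hooks)
    assay. Provides a synthetic three-channel plate-image generator with ground
    truth, per-cell segmentation (top-hat nuclei, collar cell regions, multiscale
    top-hat inclusion detection), supervised four-class phenotype gating trained
    from control wells, per-class plate normalization by Tukey median polish and
    robust Z-scores (1.4826 x MAD), threshold-based hit calling, and
    four-parameter-logistic dose-response profiling with IC50 estimation and
    mechanistic family assignment.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ranger,
    minpack.lm,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
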