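Package: tsrzone
Title: Multiperspective Tumor-Stroma Ratio Quantification in Zoned
    Histology Images
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the tumor-stroma ratio (TSR) separately in the
    inner tumor and the invasive tumor front (ITF) of calibrated,
    pancytokeratin-style stained tissue images.  Provides stain
    deconvolution and trainable pixel classification to obtain binary
    tumor/stroma masks, distance-based construction of 1-mm histological
    bands from annotated boundary curves, constrained sliding-window
    selection of the three stroma-richest image fields per band,
    TSR averaging and dichotomization at 50 percent, and the cohort-level
    statistical layer (continuity-corrected chi-square association tests,
    paired t-test, Spearman correlation, Kaplan-Meier/log-rank, Cox
    proportional hazards and logistic regression).  Includes a phantom
    generator and a proportional-hazards cohort simulator so the whole
    pipeline is testable against ground truth without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
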