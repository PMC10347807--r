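Package: medrev
Title: Medication Review Identification and Prescribing-Change Analysis for
    Primary-Care Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for analysing medication reviews in CPRD-GOLD-style
    primary-care electronic health records. Builds per-medicine prescription
    coverage intervals from issued-prescription rows, derives the maximum
    overlapping prescription count in arbitrary windows, constructs a 65-plus
    cohort with censoring at first review, identifies and classifies
    medication-review events from clinical code lists, quantifies medicines
    stopped, started and continued around a review, and fits Cox and linear
    regression models with practice-clustered robust variance. Ships a
    synthetic-data generator that emulates the source tables with planted,
    recoverable effects so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    survival,
    sandwich,
    lmtest,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
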