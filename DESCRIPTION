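Package: diabqc
Title: Quality-of-Care Indicators for Type 2 Diabetes from Electronic
    Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Three-stage evaluation of the quality of primary care for
    type 2 diabetes from routine electronic health record (EHR) extracts:
    aggregation of RAND/UCLA expert-panel ratings into an accepted indicator
    catalog; construction of an adult T2DM cohort from flat-file EHR tables
    with predefined biological-plausibility filters; and computation of
    fourteen programmable process and outcome quality-of-care indicators
    (numerator/denominator rates) per clinic and pooled. Includes a seeded
    synthetic multi-clinic EHR generator with configurable prevalences,
    missingness, implausible-value contamination and per-indicator adherence,
    so the full pipeline is testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
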