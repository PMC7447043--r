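Package: nafldphen
Title: Non-Invasive ALT-Based NAFLD Phenotyping and Genetic Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based electronic-health-record phenotyping of non-alcoholic
    fatty liver disease (NAFLD) from longitudinal alanine aminotransferase
    (ALT) measurements, with metabolic risk-factor derivation, FIB-4 and
    NAFLD fibrosis scoring, additive-genotype association models and
    trans-ethnic fixed-effects inverse-variance meta-analysis with Cochran's
    Q heterogeneity, chart-review validation metrics (positive predictive
    value and Cohen's kappa), and a seedable synthetic EHR cohort generator
    with planted genotype effects for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    e1071,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
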