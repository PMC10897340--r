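Package: ctcdtc
Title: Histology-Specific Prognostic Cutpoints for Circulating and
    Disseminated Tumor Cell Counts in Early Breast Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the secondary analysis of circulating tumor cell
    (CTC) and disseminated tumor cell (DTC) enumeration data in early-stage
    lobular versus ductal breast cancer: cohort exclusion and
    stratification, descriptive characteristics tables, raw and
    covariate-adjusted count comparisons, Monte-Carlo cross-validated
    optimization of prognostic marker thresholds with logit-method p-value
    combination, and dichotomized and combined-marker survival analyses.
    Includes a seeded synthetic-cohort generator that reproduces the
    statistical structure of such studies (zero-inflated right-skewed
    marker counts, low-event censored endpoints, optional planted hazard
    step at a marker threshold) so that every stage of the analysis is
    testable without patient-level data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
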