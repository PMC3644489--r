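Package: screenbias
Title: Cohort Construction and Estimator Comparison for Screening
    Effectiveness in Observational Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates physician-clustered screening registries with
    confounding and exposure-measurement-error structure, applies
    unselected and restricted cohort designs, and compares estimators of
    the effect of screening colonoscopy on colorectal-cancer incidence
    and mortality: unadjusted risk differences, cluster-robust logistic
    regression with marginal standardization, propensity-score quintile
    stratification, inverse-probability-of-treatment weighting, greedy
    propensity matching, and physician-preference instrumental-variable
    two-stage estimation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    survival,
    tools,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
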