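Package: ihcsig
Title: Composite Immunohistochemistry Biomarker Signatures for
    Relapse-Free Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating composite
    immunohistochemistry (IHC) biomarker signatures in survival cohorts.
    Converts digital-pathology per-cell export tables into per-core and
    per-patient H-scores and percent-positivity with core-level quality
    control, assigns St Gallen molecular subtypes from ER/PR/HER2/Ki67
    readouts, dichotomises continuous biomarker scores by median split or
    survival-optimised cutoff scanning, composes per-biomarker high/low
    calls into a summed plus/minus-one signature score, and evaluates
    signatures against relapse-free survival with Kaplan-Meier curves,
    Mantel-Cox log-rank tests, Cox proportional-hazards regression and
    fixed-horizon ROC analysis. A synthetic-cohort generator with a
    proportional-hazards relapse model makes every stage testable without
    access to patient data.
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
    purrr,
    rlang,
    readr,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
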