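Package: opioidcohort
Title: Opioid-Naive Cohorts, Chronic-Use Phenotyping, and Overdose Risk
    Models from Linked Prescription Registries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds analysis-ready cohorts from linked prescription-registry
    tables (dispensed fills, insurance enrollment spans, encounter claims,
    death records): cleans prescription monitoring data, identifies
    opioid-naive index prescriptions of short-acting hydrocodone or
    oxycodone, applies calendar-year continuous-enrollment eligibility, and
    derives morphine-milligram-equivalent exposure categories. Computes
    first-year chronic-use phenotypes from uncovered-days accounting, fatal
    and non-fatal opioid-overdose events from ICD-10 cause-of-death and
    encounter codes, and time-to-overdose records with calendar-year
    censoring. Fits multilevel logistic, Cox proportional-hazards, and
    zero-inflated negative binomial models for chronic use, overdose, drug
    switching, and cumulative dose, and ships a configurable synthetic
    linked-registry generator with known ground truth so the entire
    pipeline is testable without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    glmmTMB,
    jsonlite,
    lme4,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
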