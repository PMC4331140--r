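Package: emrcohort
Title: Dual-Source EMR Verification, Respiratory Cohort Phenotyping and
    Resource-Use Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether a linked primary-care electronic
    medical record (EMR) platform can support longitudinal respiratory
    research. Generates a synthetic adult primary-care population with
    coded asthma and COPD diagnoses, respiratory prescriptions, GP visits
    and hospitalisations; derives two independently corrupted source
    extracts and verifies their concordance (deterministic patient
    matching, prescription and diagnosis record merging, Cohen's kappa on
    condition agreement); phenotypes asthma and COPD cohorts with
    eligibility and exclusion rules; constructs moderate/severe
    exacerbation episodes and computes health-care resource-utilisation
    rates per 100 person-years with baseline-exacerbation stratification;
    and evaluates rule-based event alerts over daily batch feeds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
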