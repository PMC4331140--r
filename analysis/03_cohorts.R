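#!/usr/bin/env Rscript
## Stage 3 — phenotype the asthma and COPD cohorts and characterise them.
##
## Applies the eligibility algorithm (coded diagnosis, two or more
## bronchodilator prescriptions October 2007 - December 2008, age floor,
## exclusion diagnoses, asthma-specific severe-asthma and COPD-co-diagnosis
## exclusions) to the SIR-like extract, and writes the cohorts, the flow
## accounting, and the baseline tables.

library(emrcohort)
library(data.table)

codelist <- load_codelist()
ex <- read_extract("results/extracts/sir", codelist)

flows <- list()
for (dz in c("asthma", "copd")) {
  ch <- build_cohort(ex, cohort_spec(dz), codelist)
  print(ch)
  fwrite(ch$members, sprintf("results/cohort_%s.csv", dz), na = "")
  fwrite(ch$exclusions, sprintf("results/exclusions_%s.csv", dz))
  fwrite(baseline_table(ch), sprintf("results/baseline_%s.csv", dz))
  flows[[dz]] <- as.list(ch$flow)
}
jsonlite::write_json(flows, "results/flow.json", auto_unbox = TRUE, digits = NA)

## coded-diagnosis prevalence in the synthetic registry, overall and by sex
dx_prev <- function(cpt) {
  codes <- codelist[codelist$concept == cpt, ][["code"]]
  cases <- unique(ex$journal[code %in% codes, patient_key])
  male <- ex$patients[sex == "M", patient_key]
  prevalence(length(cases), length(intersect(cases, male)),
             nrow(ex$patients), length(male))
}
for (cpt in c("asthma_dx", "copd_dx")) {
  p <- dx_prev(cpt)
  cat(sprintf("%s prevalence: %.1f%% overall (male %.1f%%, female %.1f%%)\n",
              sub("_dx$", "", cpt), p[group == "overall", pct],
              p[group == "male", pct], p[group == "female", pct]))
}
cat("Wrote cohorts, exclusion logs, baseline tables, flow.json\n")
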