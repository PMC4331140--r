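#!/usr/bin/env Rscript
## Stage 4 — exacerbations, person-time and resource-utilisation rates.
##
## For each cohort: follow-up through 2009 censored at death or
## deregistration, exacerbation episodes from trigger records, rates per
## 100 person-years overall and stratified by baseline exacerbation
## frequency, and the hospital-days summary.

library(emrcohort)
library(data.table)

codelist <- load_codelist()
ex <- read_extract("results/extracts/sir", codelist)

summaries <- list()
for (dz in c("asthma", "copd")) {
  ch <- build_cohort(ex, cohort_spec(dz), codelist)
  fu <- person_time(ex$journal, ch$members$patient_key, codelist = codelist)
  strata <- stratify_by_baseline_exacerbations(ch)
  rt <- hru_rates(ch, ex$journal, strata = strata, codelist = codelist,
                  followup = fu)
  fwrite(rt, sprintf("results/rates_%s.csv", dz))
  summaries[[dz]] <- hospital_days_summary(ch, ex$journal, codelist = codelist,
                                           followup = fu)

  ocs <- rt[outcome == "ocs_short"]
  cat(sprintf("\n%s cohort (n = %d, %.0f person-years):\n", dz,
              nrow(ch$members), fu[, sum(person_years)]))
  cat(sprintf("  OCS short courses per 100 py: total %.1f | <=1 baseline exac %.1f | >=2 %.1f\n",
              ocs[stratum == "total", rate], ocs[stratum == "exac_le1", rate],
              ocs[stratum == "exac_ge2", rate]))
  cat(sprintf("  GP visits per 100 py: %.1f; admissions all-cause %.1f, respiratory %.1f\n",
              rt[stratum == "total" & outcome == "gp_visits", rate],
              rt[stratum == "total" & outcome == "hosp_all", rate],
              rt[stratum == "total" & outcome == "hosp_resp", rate]))
  cat(sprintf("  hospital days per patient-year: %.1f (%.0f%% respiratory)\n",
              summaries[[dz]]$mean_days_per_patient_year,
              100 * summaries[[dz]]$resp_share))
}
jsonlite::write_json(summaries, "results/hospital_days.json",
                     auto_unbox = TRUE, digits = NA)
cat("\nWrote rates_*.csv and hospital_days.json\n")
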