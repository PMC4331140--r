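#!/usr/bin/env Rscript
## Stage 1 — simulate the registry and derive the two source extracts.
##
## Generates a synthetic adult primary-care population (the ground truth
## no real extraction route ever sees) and two independently corrupted
## extracts emulating the SIR-like and Apollo-like routes, written as CSV
## pairs under results/extracts/.

library(emrcohort)

seed <- 20090101L
dir.create("results/extracts", recursive = TRUE, showWarnings = FALSE)

codelist <- load_codelist()
params <- generator_params(n_adults = 3504L, seed = seed)
truth <- generate_population(params, codelist)
print(truth)

profiles <- list(
  sir = corruption_profile(drop_patient_prob = 0.008,
                           drop_record_prob = c(prescription = 0.0001, event = 0.009),
                           seed = seed + 1L),
  apollo = corruption_profile(drop_patient_prob = 0.003,
                              drop_record_prob = c(prescription = 0.0002, event = 0.0001),
                              duplicate_record_prob = 0.0005,
                              seed = seed + 2L))

for (src in names(profiles)) {
  ex <- corrupt_to_source(truth, profiles[[src]], src)
  write_extract(ex, file.path("results/extracts", src))
  cat(sprintf("%-7s %5d patients, %6d journal records -> results/extracts/%s\n",
              src, nrow(ex$patients), nrow(ex$journal), src))
}

cat(sprintf("\nTruth: %d adults (%d asthma, %d COPD, %d comorbid), %d journal records.\n",
            nrow(truth$patients), sum(truth$patients$asthma),
            sum(truth$patients$copd),
            sum(truth$patients$asthma & truth$patients$copd),
            nrow(truth$journal)))
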