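test_that("boundary eligibility: diagnosis, exactly two bronchodilators, age 18", {
  e <- make_extract(data.frame(patient_key = "p1", age = 18L, sex = "M"),
                    list(ev("p1", "AST01", "2008-01-15"),
                         rx("p1", "SAB01", "2007-10-01"),
                         rx("p1", "SAB01", "2008-12-31")))
  ch <- build_cohort(e, cohort_spec("asthma"), CL)
  expect_equal(ch$members$patient_key, "p1")

  ## one script short fails; lowering the threshold readmits (monotonicity)
  e1 <- make_extract(e$patients, list(ev("p1", "AST01", "2008-01-15"),
                                      rx("p1", "SAB01", "2008-03-01")))
  expect_equal(nrow(build_cohort(e1, cohort_spec("asthma"), CL)$members), 0)
  expect_equal(nrow(build_cohort(e1, cohort_spec("asthma", min_bronchodilator_rx = 1),
                                 CL)$members), 1)
})

test_that("severe asthma exclusion fires on >90 days' OCS supply with overlap capping", {
  base <- list(ev("p1", "AST01", "2008-01-15"),
               rx("p1", "SAB01", "2008-02-01"), rx("p1", "SAB01", "2008-03-01"))
  pat <- data.frame(patient_key = "p1", age = 30L, sex = "F")

  ## 95 days of non-overlapping supply -> excluded, rule names severe asthma
  e <- make_extract(pat, c(base, list(rx("p1", "OCS01", "2008-03-01", days_supply = 50),
                                      rx("p1", "OCS01", "2008-04-20", days_supply = 45))))
  ch <- build_cohort(e, cohort_spec("asthma"), CL)
  expect_equal(nrow(ch$members), 0)
  expect_match(ch$exclusions[patient_key == "p1", rule], "severe asthma")

  ## two fully overlapping 60-day scripts cover only 60 calendar days -> kept
  e2 <- make_extract(pat, c(base, list(rx("p1", "OCS01", "2008-03-01", days_supply = 60),
                                       rx("p1", "OCS01", "2008-03-01", days_supply = 60))))
  expect_equal(nrow(build_cohort(e2, cohort_spec("asthma"), CL)$members), 1)

  ## supply spilling past year end is clipped at calendar coverage
  e3 <- make_extract(pat, c(base, list(rx("p1", "OCS01", "2008-12-01", days_supply = 200))))
  expect_equal(nrow(build_cohort(e3, cohort_spec("asthma"), CL)$members), 1)
})

test_that("cohort decisions on all 64 predicate combinations match the rule-by-rule oracle", {
  flags <- expand.grid(dx = c(FALSE, TRUE), rx2 = c(FALSE, TRUE),
                       adult = c(FALSE, TRUE), excl = c(FALSE, TRUE),
                       ocs90 = c(FALSE, TRUE), copd_codx = c(FALSE, TRUE))
  flags$key <- sprintf("tt%02d", seq_len(nrow(flags)))
  e <- build_eligibility_extract(flags)
  ch <- build_cohort(e, cohort_spec("asthma"), CL)
  oracle <- with(flags, dx & rx2 & adult & !excl & !ocs90 & !copd_codx)
  expect_setequal(ch$members$patient_key, flags$key[oracle])
  ## flow accounting: every candidate is included or carries a logged rule
  expect_equal(ch$flow[["included"]], sum(oracle))
  excluded_cands <- intersect(unique(ch$exclusions$patient_key),
                              flags$key[flags$dx])
  expect_equal(sum(flags$dx), ch$flow[["included"]] + length(excluded_cands))
})

test_that("COPD cohort permits and flags comorbid asthma; cohorts partition", {
  pat <- data.frame(patient_key = c("c1", "c2"), age = 60L, sex = "M")
  e <- make_extract(pat, list(
    ev("c1", "CPD01", "2007-06-01"), ev("c1", "AST01", "2006-01-01"),
    rx("c1", "LAM01", "2008-02-01"), rx("c1", "LAM01", "2008-04-01"),
    ev("c2", "CPD01", "2008-06-01"),
    rx("c2", "SAB01", "2008-02-01"), rx("c2", "SAB01", "2008-04-01")))
  copd <- build_cohort(e, cohort_spec("copd"), CL)
  expect_setequal(copd$members$patient_key, c("c1", "c2"))
  expect_equal(copd$members[patient_key == "c1", comorbid_asthma], TRUE)
  expect_equal(copd$members[patient_key == "c2", comorbid_asthma], FALSE)
  asthma <- build_cohort(e, cohort_spec("asthma"), CL)
  expect_length(intersect(asthma$members$patient_key, copd$members$patient_key), 0)
})

test_that("adding an exclusion concept never grows a cohort", {
  tr <- generate_population(generator_params(n_adults = 1200, seed = 23), CL)
  ex <- corrupt_to_source(tr, corruption_profile(seed = 1), "s")
  base <- build_cohort(ex, cohort_spec("copd", exclusion_concepts = character(0)), CL)
  more <- build_cohort(ex, cohort_spec("copd"), CL)
  expect_lte(nrow(more$members), nrow(base$members))
  expect_true(all(more$members$patient_key %in% base$members$patient_key))
})

test_that("medication classification matches direct set logic", {
  ## only SABA scripts -> SABA flag alone
  e <- make_extract(data.frame(patient_key = "m1", age = 40L, sex = "F"),
                    list(rx("m1", "SAB01", "2008-02-01")))
  f <- classify_medications(e$journal, CL)
  expect_true(f$saba); expect_false(f$ics_laba); expect_false(f$ics_mono)

  ## separate ICS and LABA inhalers count as ICS+LABA, not monotherapy
  e2 <- make_extract(data.frame(patient_key = "m2", age = 40L, sex = "F"),
                     list(rx("m2", "ICS01", "2008-02-01"),
                          rx("m2", "LAB01", "2008-07-01")))
  f2 <- classify_medications(e2$journal, CL)
  expect_true(f2$ics_laba); expect_false(f2$ics_mono)

  ## randomized prescription sets against a set-membership oracle
  set.seed(99)
  classes <- c(saba = "SAB01", laba = "LAB01", lama = "LAM01",
               ltra = "LTR01", ics = "ICS01", ics_laba = "CMB01")
  for (i in 1:20) {
    have <- names(classes)[runif(6) < 0.5]
    if (!length(have)) next
    journal <- lapply(have, function(cl) rx("px", classes[[cl]], "2008-05-01"))
    e <- make_extract(data.frame(patient_key = "px", age = 50L, sex = "M"), journal)
    f <- classify_medications(e$journal, CL)
    expect_equal(f$saba, "saba" %in% have)
    expect_equal(f$laba, "laba" %in% have)
    expect_equal(f$lama, "lama" %in% have)
    expect_equal(f$ltra, "ltra" %in% have)
    ics_laba_oracle <- ("ics_laba" %in% have) ||
      (("ics" %in% have) && ("laba" %in% have))
    expect_equal(f$ics_laba, ics_laba_oracle)
    expect_equal(f$ics_mono, ("ics" %in% have) && !ics_laba_oracle)
    expect_equal(f$any_ics, ("ics" %in% have) || ("ics_laba" %in% have))
  }
})

test_that("GOLD staging uses the conventional percent-predicted cut-offs", {
  expect_equal(gold_stage(c(80, 79.9, 61, 50, 49.9, 30, 29.9, NA)),
               c("I", "II", "II", "II", "III", "III", "IV", "unknown"))
  expect_error(gold_stage(-5), "positive")
  expect_error(gold_stage(0), "positive")
})

test_that("prevalence arithmetic and input guards", {
  p <- prevalence(100, 40, 10000, 5000)
  expect_equal(p[group == "overall", pct], 1)
  expect_equal(p[group == "female", numerator], 60)
  expect_equal(p[group == "female", pct], 100 * 60 / 5000)
  expect_error(prevalence(10, 5, 0, 0), "population")
  expect_error(prevalence(-1, 0, 100, 50), "case counts")
  expect_equal(prevalence(0, 0, 100, 50)[group == "overall", pct], 0)
})

test_that("baseline table matches a two-pass oracle and a known prescribing share", {
  ## degenerate single-member cohort: percentages are 100 or 0
  e <- make_extract(data.frame(patient_key = "p1", age = 44L, sex = "M"),
                    list(ev("p1", "CPD01", "2008-01-01"),
                         rx("p1", "LAM01", "2008-02-01"),
                         rx("p1", "LAM01", "2008-03-01"),
                         ev("p1", "SMK01", "2008-04-01", value = 1),
                         ev("p1", "FVP01", "2008-05-01", value = 61)))
  ch <- build_cohort(e, cohort_spec("copd"), CL)
  tb <- baseline_table(ch)
  expect_equal(tb[variable == "male" & stat == "pct", value], 100)
  expect_equal(tb[variable == "smoking" & level == "current" & stat == "pct", value], 100)
  expect_equal(tb[variable == "gold_stage" & level == "II" & stat == "n", value], 1)
  expect_equal(tb[variable == "med_lama" & stat == "pct", value], 100)

  ## mean/SD equal direct recomputation; ICS+LABA share near its generator
  ## probability (binomial 99% interval)
  p <- generator_params(n_adults = 2500, asthma_prevalence = 0, copd_prevalence = 1,
                        age_distribution = list(mean = 62, sd = 10, min = 41, max = 90),
                        prescribing_probabilities = list(
                          asthma = c(saba = 0, laba = 0, lama = 0, ltra = 0,
                                     ics = 0, ics_laba = 0),
                          copd = c(saba = 1, laba = 0, lama = 0.36, ltra = 0,
                                   ics = 0.15, ics_laba = 0.55)),
                        death_hazard = 0, transfer_hazard = 0, seed = 61)
  tr <- generate_population(p, CL)
  ex <- corrupt_to_source(tr, corruption_profile(seed = 1), "s")
  ch <- build_cohort(ex, cohort_spec("copd"), CL)
  n <- nrow(ch$members)
  expect_gt(n, 1500)
  tb <- baseline_table(ch)
  age_mean <- tb[variable == "age" & stat == "mean", value]
  expect_equal(age_mean, sum(ch$members$age) / n)
  age_sd <- tb[variable == "age" & stat == "sd", value]
  expect_equal(age_sd, sqrt(sum((ch$members$age - age_mean)^2) / (n - 1)))
  share <- tb[variable == "med_ics_laba" & stat == "n", value]
  expect_gte(share, qbinom(0.005, n, 0.55))
  expect_lte(share, qbinom(0.995, n, 0.55))
})
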