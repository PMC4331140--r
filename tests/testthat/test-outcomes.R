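defn_copd <- exacerbation_definition("copd")
defn_asthma <- exacerbation_definition("asthma")

test_that("trigger records merge into episodes by the 14-day rule with severity", {
  jr <- make_extract(data.frame(patient_key = "p", age = 60L, sex = "M"),
                     list(rx("p", "OCS01", "2009-01-01", days_supply = 5),
                          rx("p", "ABX01", "2009-01-06", days_supply = 7)))$journal
  ep <- identify_exacerbations(jr, defn_copd, codelist = CL)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$severity, "moderate")
  expect_equal(ep$n_records, 2)

  ## OCS then respiratory admission 3 days later: one severe episode
  jr2 <- make_extract(data.frame(patient_key = "p", age = 60L, sex = "M"),
                      list(rx("p", "OCS01", "2009-02-01", days_supply = 5),
                           ev("p", "RAD01", "2009-02-04",
                              discharge_date = "2009-02-08")))$journal
  ep2 <- identify_exacerbations(jr2, defn_copd, codelist = CL)
  expect_equal(nrow(ep2), 1)
  expect_equal(ep2$severity, "severe")
  expect_equal(as.character(ep2$end_date), "2009-02-08")

  ## a record inside an admission's stay joins that episode even after 14 days
  jr3 <- make_extract(data.frame(patient_key = "p", age = 60L, sex = "M"),
                      list(ev("p", "RAD01", "2009-03-01", discharge_date = "2009-03-25"),
                           rx("p", "OCS01", "2009-03-20", days_supply = 5)))$journal
  expect_equal(nrow(identify_exacerbations(jr3, defn_copd, codelist = CL)), 1)

  ## events 15 days apart split into two moderate episodes
  jr4 <- make_extract(data.frame(patient_key = "p", age = 60L, sex = "M"),
                      list(rx("p", "OCS01", "2009-04-01", days_supply = 5),
                           rx("p", "OCS01", "2009-04-16", days_supply = 5)))$journal
  expect_equal(nrow(identify_exacerbations(jr4, defn_copd, codelist = CL)), 2)

  ## antibiotics trigger COPD but not asthma episodes; maintenance OCS never does
  jr5 <- make_extract(data.frame(patient_key = "p", age = 60L, sex = "M"),
                      list(rx("p", "ABX01", "2009-05-01", days_supply = 7),
                           rx("p", "OCS01", "2009-07-01", days_supply = 28)))$journal
  expect_equal(nrow(identify_exacerbations(jr5, defn_copd, codelist = CL)), 1)
  expect_equal(nrow(identify_exacerbations(jr5, defn_asthma, codelist = CL)), 0)

  expect_equal(nrow(identify_exacerbations(jr5[0], defn_copd, codelist = CL)), 0)
})

test_that("episode merging invariants hold on randomized record sets", {
  set.seed(17)
  for (i in 1:15) {
    n <- sample(1:25, 1)
    dates <- as.character(data.table::as.IDate("2009-01-01") +
                            sample(0:364, n, replace = TRUE))
    jr <- make_extract(data.frame(patient_key = "p", age = 60L, sex = "M"),
                       lapply(dates, function(d) rx("p", "OCS01", d, days_supply = 5)))$journal
    d0 <- exacerbation_definition("copd", merge_window_days = 0)
    ep0 <- identify_exacerbations(jr, d0, codelist = CL)
    expect_equal(nrow(ep0), length(unique(dates)))
    dInf <- exacerbation_definition("copd", merge_window_days = Inf)
    epInf <- identify_exacerbations(jr, dInf, codelist = CL)
    expect_lte(nrow(epInf), 1)
    d14 <- identify_exacerbations(jr, defn_copd, codelist = CL)
    expect_lte(nrow(d14), n)          # episodes never exceed trigger records
    expect_gte(nrow(d14), nrow(epInf))
  }
})

test_that("person-time censors at the earliest of death, deregistration and year end", {
  pat <- data.frame(patient_key = c("full", "died", "moved", "both"),
                    age = 50L, sex = "F")
  e <- make_extract(pat, list(
    ev("died", "DTH01", "2009-07-02"),
    ev("moved", "DRG01", "2009-03-01"),
    ev("both", "DRG01", "2009-05-01"), ev("both", "DTH01", "2009-09-01")))
  fu <- person_time(e$journal, pat$patient_key, codelist = CL)
  expect_equal(fu[patient_key == "full", person_years], 365 / 365.25)
  expect_equal(fu[patient_key == "full", exit_reason], "admin_end")
  expect_equal(fu[patient_key == "died", person_years], 182 / 365.25)
  expect_equal(fu[patient_key == "died", exit_reason], "death")
  expect_equal(fu[patient_key == "moved", exit_reason], "deregistration")
  ## earliest event wins
  expect_equal(fu[patient_key == "both", exit_reason], "deregistration")

  ## death before entry: zero person-years, flagged via reason + exit date
  e2 <- make_extract(data.frame(patient_key = "pre", age = 50L, sex = "F"),
                     list(ev("pre", "DTH01", "2008-06-01")))
  fu2 <- person_time(e2$journal, "pre", codelist = CL)
  expect_equal(fu2$person_years, 0)
  expect_equal(fu2$exit_reason, "death")

  ## random exit sets against a min() oracle
  set.seed(5)
  for (i in 1:10) {
    dd <- sample(c(NA, sample(0:400, 1)), 1)
    rg <- sample(c(NA, sample(0:400, 1)), 1)
    journal <- list()
    if (!is.na(dd)) journal <- c(journal, list(ev("q", "DTH01",
      as.character(data.table::as.IDate("2009-01-01") + dd))))
    if (!is.na(rg)) journal <- c(journal, list(ev("q", "DRG01",
      as.character(data.table::as.IDate("2009-01-01") + rg))))
    e3 <- make_extract(data.frame(patient_key = "q", age = 50L, sex = "M"), journal)
    fu3 <- person_time(e3$journal, "q", codelist = CL)
    oracle_days <- min(dd, rg, 365, na.rm = TRUE)
    expect_equal(fu3$person_years, min(oracle_days, 365) / 365.25)
  }
})

test_that("rate arithmetic, the OCS outlier rule, and stratification", {
  pat <- data.frame(patient_key = c("r1", "r2", "out"), age = 45L, sex = "M")
  journal <- list(
    ev("r1", "AST01", "2008-01-01"), rx("r1", "SAB01", "2008-02-01"),
    rx("r1", "SAB01", "2008-03-01"),
    ev("r2", "AST01", "2008-01-01"), rx("r2", "SAB01", "2008-02-01"),
    rx("r2", "SAB01", "2008-03-01"),
    ev("out", "AST01", "2008-01-01"), rx("out", "SAB01", "2008-02-01"),
    rx("out", "SAB01", "2008-03-01"),
    ## follow-up year OCS short courses: 2 for r1, 1 for r2, 4 for out
    rx("r1", "OCS01", "2009-02-01", days_supply = 5),
    rx("r1", "OCS01", "2009-06-01", days_supply = 5),
    rx("r2", "OCS01", "2009-03-01", days_supply = 5),
    rx("out", "OCS01", "2009-01-10", days_supply = 5),
    rx("out", "OCS01", "2009-04-10", days_supply = 5),
    rx("out", "OCS01", "2009-07-10", days_supply = 5),
    rx("out", "OCS01", "2009-10-10", days_supply = 5))
  ## 13 baseline OCS scripts make "out" an outlier for the OCS row only
  for (k in 0:12) {
    journal <- c(journal, list(rx("out", "OCS01",
                                  as.character(data.table::as.IDate("2008-01-05") + 25 * k),
                                  days_supply = 5)))
  }
  e <- make_extract(pat, journal)
  ## keep "out" in the cohort: 13 five-day courses cover 65 days, under 90
  ch <- build_cohort(e, cohort_spec("asthma"), CL)
  expect_setequal(ch$members$patient_key, c("r1", "r2", "out"))
  rt <- hru_rates(ch, e$journal, codelist = CL)
  ocs <- rt[outcome == "ocs_short" & stratum == "total"]
  expect_equal(ocs$n_patients, 2)        # outlier excluded from this row
  expect_equal(ocs$events, 3)            # 2 + 1, the outlier's 4 not counted
  expect_equal(ocs$person_years, 2 * 365 / 365.25)
  expect_equal(ocs$rate, 100 * 3 / (2 * 365 / 365.25))
  ## other rows keep all three patients and their person-years
  gp <- rt[outcome == "gp_visits" & stratum == "total"]
  expect_equal(gp$n_patients, 3)
  expect_equal(gp$person_years, 3 * 365 / 365.25)
  expect_equal(rt[outcome == "antibiotics" & stratum == "total", rate], 0)

  ## baseline exacerbations: "out" has 13 distinct course dates but 5-day
  ## supplies 25 days apart merge nothing -> 13 episodes; r1/r2 have none
  strata <- stratify_by_baseline_exacerbations(ch)
  expect_setequal(strata$exac_le1, c("r1", "r2"))
  expect_setequal(strata$exac_ge2, "out")
  expect_setequal(c(strata$exac_le1, strata$exac_ge2), strata$total)
})

test_that("stratification splits counts at the <=1 / >=2 boundary", {
  ch <- structure(list(disease = "asthma",
                       members = data.table::data.table(
                         patient_key = c("a", "b", "c", "d"),
                         baseline_exacerbation_count = c(0L, 1L, 2L, 5L),
                         ics_mono = c(TRUE, FALSE, FALSE, FALSE),
                         ics_laba = c(FALSE, TRUE, FALSE, FALSE),
                         laba = FALSE, lama = FALSE)),
                  class = "emr_cohort")
  s <- stratify_by_baseline_exacerbations(ch)
  expect_setequal(s$exac_le1, c("a", "b"))
  expect_setequal(s$exac_ge2, c("c", "d"))
  expect_setequal(s$med_subset, c("a", "b"))
})

test_that("hospital-days summary sums clipped stays", {
  pat <- data.frame(patient_key = c("h1", "h2"), age = 60L, sex = "F")
  e <- make_extract(pat, list(
    ev("h1", "CPD01", "2007-06-01"), rx("h1", "LAM01", "2008-02-01"),
    rx("h1", "LAM01", "2008-03-01"),
    ev("h2", "CPD01", "2007-06-01"), rx("h2", "LAM01", "2008-02-01"),
    rx("h2", "LAM01", "2008-03-01"),
    ## h1: one 3-day respiratory stay
    ev("h1", "RAD01", "2009-05-01", discharge_date = "2009-05-04"),
    ## h2: non-respiratory stay spanning death -> clipped at exit
    ev("h2", "NAD01", "2009-06-25", discharge_date = "2009-07-20"),
    ev("h2", "DTH01", "2009-07-01")))
  ch <- build_cohort(e, cohort_spec("copd"), CL)
  hd <- hospital_days_summary(ch, e$journal, codelist = CL)
  ## h1 contributes 3 days, h2 is clipped at the death boundary (6 days)
  expect_equal(hd$total_days, 9)
  expect_equal(hd$resp_days, 3)
  expect_equal(hd$resp_share, 1 / 3)
  py <- 365 / 365.25 + 181 / 365.25
  expect_equal(hd$person_years, py)
  expect_equal(hd$mean_days_per_patient_year, 9 / py)

  ## random stays against an interval-sum oracle (no censoring)
  set.seed(31)
  for (i in 1:8) {
    n <- sample(1:6, 1)
    starts <- sample(0:300, n, replace = TRUE)
    lens <- sample(1:15, n, replace = TRUE)
    journal <- list(ev("z", "CPD01", "2007-06-01"),
                    rx("z", "LAM01", "2008-02-01"), rx("z", "LAM01", "2008-03-01"))
    for (j in seq_len(n)) {
      d0 <- data.table::as.IDate("2009-01-01") + starts[j]
      journal <- c(journal, list(ev("z", "NAD01", as.character(d0),
                                    discharge_date = as.character(d0 + lens[j]))))
    }
    ez <- make_extract(data.frame(patient_key = "z", age = 60L, sex = "M"), journal)
    chz <- build_cohort(ez, cohort_spec("copd"), CL)
    hdz <- hospital_days_summary(chz, ez$journal, codelist = CL)
    expect_equal(hdz$total_days, sum(pmin(starts + lens, 365) - starts))
  }
})

test_that("validation errors: discharge before admission", {
  pat <- data.frame(patient_key = "v", age = 60L, sex = "F")
  jr <- make_extract(pat, list(ev("v", "CPD01", "2007-06-01"),
                               rx("v", "LAM01", "2008-02-01"),
                               rx("v", "LAM01", "2008-03-01"),
                               ev("v", "NAD01", "2009-05-10")))$journal
  ## force an inconsistent discharge on the in-memory table
  jr[code == "NAD01", discharge_date := data.table::as.IDate("2009-05-01")]
  ch <- build_cohort(make_extract(pat, list(ev("v", "CPD01", "2007-06-01"),
                                            rx("v", "LAM01", "2008-02-01"),
                                            rx("v", "LAM01", "2008-03-01"))),
                     cohort_spec("copd"), CL)
  expect_error(hospital_days_summary(ch, jr, codelist = CL), "discharge")
})
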