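#' Declarative phenotype definition for an asthma or COPD cohort
#'
#' Encodes the eligibility algorithm: a coded diagnosis during or before
#' the baseline year, evidence of current disease activity (a minimum
#' number of inhaled bronchodilator prescriptions in a window), an age
#' floor, exclusion diagnoses, and — for asthma only — exclusion of
#' severe asthma (more than 90 days' supply of oral corticosteroid during
#' the baseline year) and of COPD co-diagnosis. The COPD cohort permits a
#' co-diagnosis of asthma and flags it.
#'
#' All windows are half-open `[start, end)`.
#'
#' @param disease `"asthma"` or `"copd"`.
#' @param min_bronchodilator_rx minimum bronchodilator prescriptions
#'   (combination ICS/LABA inhalers count: they contain a long-acting
#'   bronchodilator).
#' @param rx_window prescription window (default October 2007 through
#'   December 2008).
#' @param min_age minimum age in years at `age_reference_date`
#'   (default 18 for asthma, 40 for COPD).
#' @param age_reference_date date at which age is evaluated; the patient
#'   file states age as of this date.
#' @param exclusion_concepts diagnosis concepts that exclude a patient
#'   when coded inside `exclusion_window`.
#' @param exclusion_window window for the exclusion diagnoses (default
#'   calendar 2008--2009).
#' @param baseline_year_window the baseline year (default calendar 2008),
#'   used for the OCS-supply rule and baseline characterisation.
#' @param ocs_supply_gt_days asthma only: exclude when the union of OCS
#'   supply intervals within the baseline year exceeds this many days.
#' @param exclude_copd_codx asthma only: exclude on any COPD diagnosis.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(disease = c("asthma", "copd"),
                        min_bronchodilator_rx = 2L,
                        rx_window = c("2007-10-01", "2009-01-01"),
                        min_age = NULL,
                        age_reference_date = "2008-12-31",
                        exclusion_concepts = c("cystic_fibrosis_dx", "lung_cancer_dx",
                                               "bronchiectasis_dx", "fibrotic_lung_dx"),
                        exclusion_window = c("2008-01-01", "2010-01-01"),
                        baseline_year_window = c("2008-01-01", "2009-01-01"),
                        ocs_supply_gt_days = 90L,
                        exclude_copd_codx = TRUE) {
  disease <- match.arg(disease)
  if (is.null(min_age)) min_age <- if (disease == "asthma") 18L else 40L
  spec <- list(
    disease = disease,
    diagnosis_concepts = paste0(disease, "_dx"),
    min_bronchodilator_rx = check_count(min_bronchodilator_rx,
                                        "min_bronchodilator_rx", min = 1L),
    rx_window = as_window(rx_window, "rx_window"),
    min_age = check_count(min_age, "min_age"),
    age_reference_date = as_idate(age_reference_date),
    exclusion_concepts = exclusion_concepts,
    exclusion_window = as_window(exclusion_window, "exclusion_window"),
    baseline_year_window = as_window(baseline_year_window, "baseline_year_window"),
    ocs_supply_gt_days = check_count(ocs_supply_gt_days, "ocs_supply_gt_days"),
    exclude_copd_codx = isTRUE(exclude_copd_codx)
  )
  structure(spec, class = "cohort_spec")
}

#' Build a disease cohort from a source extract
#'
#' Applies the eligibility rules of a [cohort_spec()] in order (diagnosis;
#' bronchodilator prescriptions; age; exclusion diagnoses; asthma-specific
#' exclusions), logging every exclusion with the rule that fired and
#' keeping flow counts at each step, then characterises the included
#' patients at baseline (demographics, smoking, BMI band, first baseline
#' lung-function measurements, GOLD stage for COPD, medication-class
#' flags, cardiovascular comorbidity flags, and the number of baseline
#' exacerbation episodes used for stratification).
#'
#' @param extract a `source_extract`.
#' @param spec a [cohort_spec()].
#' @param codelist the code list.
#' @param merge_window_days episode-merge window handed to
#'   [identify_exacerbations()] for the baseline exacerbation count.
#' @return an `emr_cohort`: list with `disease`, `spec`, `members` (one
#'   row per included patient), `flow` (named step counts), and
#'   `exclusions` (`data.table(patient_key, rule)`).
#' @export
build_cohort <- function(extract, spec, codelist = load_codelist(),
                         merge_window_days = 14L) {
  validate_extract(extract)
  stopifnot(inherits(spec, "cohort_spec"))
  jr <- extract$journal
  b0 <- spec$baseline_year_window[1L]
  b1 <- spec$baseline_year_window[2L]

  flow <- c()
  exclusions <- list()
  log_excl <- function(keys, rule) {
    if (length(keys)) {
      exclusions[[length(exclusions) + 1L]] <<- data.table(patient_key = keys,
                                                           rule = rule)
    }
  }

  ## 1. coded diagnosis during or before the baseline year
  dx_codes <- concept_codes(codelist, spec$diagnosis_concepts)
  cand <- unique(jr[record_kind == "event" & code %in% dx_codes & date < b1,
                    patient_key])
  flow["diagnosed"] <- length(cand)

  ## 2. >= min bronchodilator prescriptions in the activity window
  bd_codes <- concept_codes(codelist, bronchodilator_concepts())
  bd_n <- jr[patient_key %in% cand & record_kind == "prescription" &
               code %in% bd_codes & in_window(date, spec$rx_window),
             .N, by = patient_key]
  ok <- bd_n[N >= spec$min_bronchodilator_rx, patient_key]
  log_excl(setdiff(cand, ok), sprintf("fewer than %d bronchodilator prescriptions in window",
                                      spec$min_bronchodilator_rx))
  cand <- ok
  flow["active_rx"] <- length(cand)

  ## 3. age floor at the reference date (patient-file age is as of it)
  ages <- extract$patients[match(cand, patient_key), age]
  ok <- cand[!is.na(ages) & ages >= spec$min_age]
  log_excl(setdiff(cand, ok), sprintf("aged under %d", spec$min_age))
  cand <- ok
  flow["age_eligible"] <- length(cand)

  ## 4. exclusion diagnoses inside the exclusion window
  if (length(spec$exclusion_concepts)) {
    ex_codes <- concept_codes(codelist, spec$exclusion_concepts)
    hit <- unique(jr[patient_key %in% cand & record_kind == "event" &
                       code %in% ex_codes & in_window(date, spec$exclusion_window),
                     patient_key])
    log_excl(hit, "exclusion diagnosis (cystic fibrosis / lung cancer / bronchiectasis / fibrotic lung disease)")
    cand <- setdiff(cand, hit)
  }
  flow["no_exclusion_dx"] <- length(cand)

  comorbid_asthma <- NULL
  if (spec$disease == "asthma") {
    ## 5a. severe asthma: > ocs_supply_gt_days days' OCS supply in the
    ##     baseline year, overlapping scripts capped at calendar coverage
    ocs_codes <- concept_codes(codelist, "ocs")
    ocs <- jr[patient_key %in% cand & record_kind == "prescription" &
                code %in% ocs_codes & in_window(date, spec$baseline_year_window) &
                !is.na(days_supply)]
    supply <- ocs[, .(days = interval_union_days(date, days_supply,
                                                 clip = c(b0, b1))),
                  by = patient_key]
    hit <- supply[days > spec$ocs_supply_gt_days, patient_key]
    log_excl(hit, sprintf("severe asthma (>%d days' supply of OCS during baseline year)",
                          spec$ocs_supply_gt_days))
    cand <- setdiff(cand, hit)
    flow["no_severe_asthma"] <- length(cand)

    ## 5b. COPD co-diagnosis excludes from the asthma cohort
    if (spec$exclude_copd_codx) {
      copd_codes <- concept_codes(codelist, "copd_dx")
      hit <- unique(jr[patient_key %in% cand & record_kind == "event" &
                         code %in% copd_codes, patient_key])
      log_excl(hit, "co-diagnosis of COPD")
      cand <- setdiff(cand, hit)
    }
    flow["no_copd_codx"] <- length(cand)
  } else {
    ## COPD cohort: asthma co-diagnosis is permitted and flagged
    asthma_codes <- concept_codes(codelist, "asthma_dx")
    comorbid_asthma <- unique(jr[patient_key %in% cand & record_kind == "event" &
                                   code %in% asthma_codes, patient_key])
  }
  flow["included"] <- length(cand)

  members <- characterise_members(extract, cand, spec, codelist,
                                  comorbid_asthma, merge_window_days)
  exclusions <- if (length(exclusions)) data.table::rbindlist(exclusions) else {
    data.table(patient_key = character(0), rule = character(0))
  }
  structure(list(disease = spec$disease, spec = spec, members = members,
                 flow = flow, exclusions = exclusions),
            class = "emr_cohort")
}

## baseline attributes for included patients
characterise_members <- function(extract, keys, spec, codelist,
                                 comorbid_asthma, merge_window_days) {
  jr <- extract$journal[patient_key %in% keys]
  bwin <- spec$baseline_year_window
  base <- extract$patients[patient_key %in% keys, .(patient_key, age, sex)]

  latest_value <- function(cpt) {
    codes <- concept_codes(codelist, cpt)
    jr[record_kind == "event" & code %in% codes & date < bwin[2L]
       ][order(date, record_id)][, .(value = value[.N]), by = patient_key]
  }
  ## first baseline measurement; tie on date -> lowest record id
  first_value <- function(cpt) {
    codes <- concept_codes(codelist, cpt)
    jr[record_kind == "event" & code %in% codes & in_window(date, bwin)
       ][order(date, record_id)][, .(value = value[1L]), by = patient_key]
  }

  smk <- latest_value("smoking_status")
  smk[, smoking := c("current", "former", "never")[value]]
  base <- merge(base, smk[, .(patient_key, smoking)], by = "patient_key", all.x = TRUE)
  base[is.na(smoking), smoking := "unknown"]

  bmi <- latest_value("bmi")
  bmi[, bmi_category := cut(value, breaks = c(-Inf, 18, 26, 31, Inf),
                            labels = c("<18", "18-25", "26-30", ">30"),
                            right = FALSE)]
  base <- merge(base, bmi[, .(patient_key, bmi_category = as.character(bmi_category))],
                by = "patient_key", all.x = TRUE)
  base[is.na(bmi_category), bmi_category := "unknown"]

  fv <- first_value("fev1")
  base <- merge(base, fv[, .(patient_key, fev1_L = value)], by = "patient_key", all.x = TRUE)
  fp <- first_value("fev1_pct_pred")
  base <- merge(base, fp[, .(patient_key, fev1_pct_pred = value)], by = "patient_key", all.x = TRUE)
  if (spec$disease == "copd") {
    base[, gold_stage := gold_stage(fev1_pct_pred)]
  } else {
    base[, gold_stage := NA_character_]
    pef <- first_value("pef")
    base <- merge(base, pef[, .(patient_key, pef = value)], by = "patient_key", all.x = TRUE)
  }

  med <- classify_medications(extract$journal, codelist, window = bwin)
  base <- merge(base, med, by = "patient_key", all.x = TRUE)
  for (cl in setdiff(names(med), "patient_key")) {
    base[is.na(get(cl)), (cl) := FALSE]
  }

  ## cardiovascular comorbidities coded before the end of follow-up
  cv <- c(mi = "mi_dx", hypertension = "hypertension_dx",
          stroke = "stroke_dx", heart_failure = "heart_failure_dx")
  cv_end <- as_idate("2010-01-01")
  for (nm in names(cv)) {
    codes <- concept_codes(codelist, cv[[nm]])
    hit <- unique(jr[record_kind == "event" & code %in% codes & date < cv_end,
                     patient_key])
    base[, (paste0("cm_", nm)) := patient_key %in% hit]
  }
  base[, cm_any_cv := cm_mi | cm_hypertension | cm_stroke | cm_heart_failure]

  ## baseline-year exacerbation episodes (same algorithm as follow-up)
  defn <- exacerbation_definition(spec$disease, merge_window_days = merge_window_days)
  ep <- identify_exacerbations(jr, defn, window = bwin, codelist = codelist)
  cnt <- ep[, .N, by = patient_key]
  base <- merge(base, cnt[, .(patient_key, baseline_exacerbation_count = N)],
                by = "patient_key", all.x = TRUE)
  base[is.na(baseline_exacerbation_count), baseline_exacerbation_count := 0L]

  if (!is.null(comorbid_asthma)) {
    base[, comorbid_asthma := patient_key %in% comorbid_asthma]
  }
  data.table::setorder(base, patient_key)
  base[]
}

#' @export
print.emr_cohort <- function(x, ...) {
  cat(sprintf("<emr_cohort '%s'> %d members\n", x$disease, nrow(x$members)))
  cat("  flow: ", paste(sprintf("%s=%d", names(x$flow), x$flow), collapse = " -> "), "\n")
  invisible(x)
}

#' Per-patient medication-class flags over a window
#'
#' Flags each patient's prescribed classes in the window: SABA, LABA,
#' LAMA, LTRA; `ics_laba` for a combination product or co-prescription of
#' ICS and LABA; `ics_mono` for ICS without any LABA exposure; and
#' `ics_ltra_lama` for ICS (not counted as ICS+LABA) together with an
#' LTRA or LAMA. `any_ics` is the union of the ICS-containing flags.
#'
#' @param journal a journal `data.table` (as in a `source_extract`).
#' @param codelist the code list.
#' @param window half-open date window (default calendar 2008).
#' @return `data.table` of logical flags, one row per patient with any
#'   prescription in the window.
#' @export
classify_medications <- function(journal, codelist = load_codelist(),
                                 window = c("2008-01-01", "2009-01-01")) {
  window <- as_window(window, "window")
  rx <- journal[record_kind == "prescription" & in_window(date, window)]
  cls_of <- stats::setNames(codelist$concept, codelist$code)
  rx[, concept := cls_of[code]]
  has <- function(cpt) rx[concept == cpt, unique(patient_key)]
  keys <- rx[, unique(patient_key)]
  out <- data.table(patient_key = keys)
  out[, saba := patient_key %in% has("saba")]
  out[, laba := patient_key %in% has("laba")]
  out[, lama := patient_key %in% has("lama")]
  out[, ltra := patient_key %in% has("ltra")]
  ics_prod <- out$patient_key %in% has("ics")
  combo <- out$patient_key %in% has("ics_laba")
  out[, ics_laba := combo | (ics_prod & laba)]
  out[, ics_mono := ics_prod & !ics_laba]
  out[, ics_ltra_lama := ics_prod & !ics_laba & (ltra | lama)]
  out[, any_ics := ics_prod | combo]
  data.table::setorder(out, patient_key)
  out[]
}

#' Spirometric COPD severity grade from FEV1 percent predicted
#'
#' Conventional cut-offs: stage I >= 80, II 50--79, III 30--49, IV < 30
#' percent predicted; missing values grade as `"unknown"`.
#'
#' @param fev1_pct_pred numeric vector of FEV1 percent-predicted values
#'   (positive; `NA` allowed).
#' @return character vector of `"I"`, `"II"`, `"III"`, `"IV"`, `"unknown"`.
#' @export
#' @examples
#' gold_stage(c(95, 61, 42, 25, NA))
gold_stage <- function(fev1_pct_pred) {
  x <- as.numeric(fev1_pct_pred)
  if (any(!is.na(x) & (x <= 0 | !is.finite(x)))) {
    stop("fev1_pct_pred must be positive", call. = FALSE)
  }
  out <- rep("unknown", length(x))
  out[!is.na(x) & x >= 80] <- "I"
  out[!is.na(x) & x >= 50 & x < 80] <- "II"
  out[!is.na(x) & x >= 30 & x < 50] <- "III"
  out[!is.na(x) & x < 30] <- "IV"
  out
}

#' Disease prevalence overall and by sex
#'
#' Pure arithmetic on case and population counts, so it can be driven
#' either from built cohorts or from externally reported counts.
#'
#' @param n_cases,n_cases_male total and male case counts.
#' @param n_pop,n_pop_male total and male population counts.
#' @return `data.table` with rows `overall`, `male`, `female`: numerator,
#'   denominator, `proportion` and `pct` (unrounded percentage).
#' @export
#' @examples
#' prevalence(7981, 3209, 180493, 90706)
prevalence <- function(n_cases, n_cases_male, n_pop, n_pop_male) {
  if (n_pop <= 0 || n_pop_male <= 0 || n_pop_male >= n_pop) {
    stop("population counts must be positive with 0 < male < total", call. = FALSE)
  }
  if (n_cases < 0 || n_cases_male < 0 || n_cases_male > n_cases || n_cases > n_pop) {
    stop("case counts inconsistent with population", call. = FALSE)
  }
  num <- c(overall = n_cases, male = n_cases_male, female = n_cases - n_cases_male)
  den <- c(overall = n_pop, male = n_pop_male, female = n_pop - n_pop_male)
  data.table(group = names(num), numerator = as.numeric(num),
             denominator = as.numeric(den),
             proportion = as.numeric(num / den),
             pct = as.numeric(100 * num / den))
}

#' Baseline characterisation table for a cohort
#'
#' Summarises the members of an [build_cohort()] result row-type by
#' row-type: counts and percentages for categorical characteristics
#' (sex, smoking, BMI band, GOLD stage, medication classes,
#' cardiovascular comorbidities) and mean/SD for continuous ones (age,
#' FEV1, FEV1 percent predicted, PEF for asthma).
#'
#' @param cohort an `emr_cohort` with at least one member.
#' @return long-format `data.table(variable, level, stat, value)`.
#' @export
baseline_table <- function(cohort) {
  stopifnot(inherits(cohort, "emr_cohort"))
  m <- cohort$members
  if (nrow(m) == 0L) stop("cohort has no members", call. = FALSE)
  n <- nrow(m)
  rows <- list(data.table(variable = "n", level = "", stat = "n", value = n))
  add_mean_sd <- function(variable, x) {
    x <- x[!is.na(x)]
    rows[[length(rows) + 1L]] <<- data.table(
      variable = variable, level = "",
      stat = c("mean", "sd", "n_obs"),
      value = c(mean(x), stats::sd(x), length(x)))
  }
  add_cat <- function(variable, x, levels) {
    cnt <- vapply(levels, function(l) sum(x == l, na.rm = TRUE), numeric(1))
    rows[[length(rows) + 1L]] <<- data.table(
      variable = variable, level = rep(levels, each = 2L),
      stat = rep(c("n", "pct"), times = length(levels)),
      value = as.vector(rbind(cnt, 100 * cnt / n)))
  }
  add_flag <- function(variable, x) {
    k <- sum(x, na.rm = TRUE)
    rows[[length(rows) + 1L]] <<- data.table(
      variable = variable, level = "", stat = c("n", "pct"),
      value = c(k, 100 * k / n))
  }
  add_mean_sd("age", m$age)
  add_flag("male", m$sex == "M")
  add_cat("smoking", m$smoking, c("current", "former", "never", "unknown"))
  add_cat("bmi", m$bmi_category, c("<18", "18-25", "26-30", ">30", "unknown"))
  add_mean_sd("fev1_L", m$fev1_L)
  add_mean_sd("fev1_pct_pred", m$fev1_pct_pred)
  if (cohort$disease == "copd") {
    add_cat("gold_stage", m$gold_stage, c("I", "II", "III", "IV", "unknown"))
  } else if ("pef" %in% names(m)) {
    add_mean_sd("pef", m$pef)
  }
  for (cl in c("saba", "laba", "lama", "ltra", "ics_mono", "ics_laba",
               "ics_ltra_lama")) {
    add_flag(paste0("med_", cl), m[[cl]])
  }
  for (cm in c("cm_any_cv", "cm_mi", "cm_hypertension", "cm_stroke",
               "cm_heart_failure")) {
    add_flag(cm, m[[cm]])
  }
  if ("comorbid_asthma" %in% names(m)) add_flag("comorbid_asthma", m$comorbid_asthma)
  data.table::rbindlist(rows)
}
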