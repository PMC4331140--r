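#' Exacerbation episode definition
#'
#' Trigger records for a moderate/severe exacerbation: a short course of
#' oral corticosteroid and/or a respiratory hospitalisation for asthma,
#' plus antibiotic courses for COPD. Trigger records closer together than
#' `merge_window_days` are merged into one clinical episode; an episode
#' containing any respiratory admission is severe, otherwise moderate.
#' OCS triggers are restricted to short courses (`days_supply <=
#' ocs_short_course_max_days`) so maintenance steroid therapy does not
#' register as a monthly exacerbation.
#'
#' @param disease `"asthma"` or `"copd"`.
#' @param merge_window_days non-negative merge window in days (may be
#'   `Inf`); 14 by convention.
#' @param ocs_short_course_max_days OCS scripts with longer supply are
#'   treated as maintenance, not triggers; scripts without a recorded
#'   supply count as short courses.
#' @return an `exacerbation_definition` list.
#' @export
exacerbation_definition <- function(disease = c("asthma", "copd"),
                                    merge_window_days = 14L,
                                    ocs_short_course_max_days = 21L) {
  disease <- match.arg(disease)
  if (!is.numeric(merge_window_days) || length(merge_window_days) != 1L ||
      is.na(merge_window_days) || merge_window_days < 0) {
    stop("merge_window_days must be >= 0 (Inf allowed)", call. = FALSE)
  }
  triggers <- if (disease == "asthma") c("ocs", "resp_admission") else
    c("ocs", "antibiotic", "resp_admission")
  structure(list(disease = disease, trigger_concepts = triggers,
                 merge_window_days = merge_window_days,
                 ocs_short_course_max_days =
                   check_count(ocs_short_course_max_days,
                               "ocs_short_course_max_days", min = 1L)),
            class = "exacerbation_definition")
}

#' Construct exacerbation episodes from journal records
#'
#' Sorts each patient's trigger records by date and groups them: a record
#' starting no more than `merge_window_days` after the running episode's
#' end joins that episode (admissions extend the end to their discharge
#' date), otherwise it starts a new one.
#'
#' @param journal journal `data.table` with `record_id`.
#' @param defn an [exacerbation_definition()].
#' @param window half-open observation window.
#' @param codelist the code list.
#' @return `data.table(patient_key, start_date, end_date, severity,
#'   n_records, record_ids)`; `severity` is `"severe"` iff a respiratory
#'   admission is a component, `record_ids` is comma-separated.
#' @export
identify_exacerbations <- function(journal, defn,
                                   window = c("2009-01-01", "2010-01-01"),
                                   codelist = load_codelist()) {
  stopifnot(inherits(defn, "exacerbation_definition"))
  window <- as_window(window, "window")
  cpt_of <- stats::setNames(codelist$concept, codelist$code)
  tr <- journal[cpt_of[code] %in% defn$trigger_concepts &
                  in_window(date, window)]
  empty <- data.table(patient_key = character(0),
                      start_date = as_idate(character(0)),
                      end_date = as_idate(character(0)),
                      severity = character(0), n_records = integer(0),
                      record_ids = character(0))
  if (!nrow(tr)) return(empty)
  tr[, concept := cpt_of[code]]
  ## drop maintenance OCS scripts
  tr <- tr[!(concept == "ocs" & !is.na(days_supply) &
               days_supply > defn$ocs_short_course_max_days)]
  if (!nrow(tr)) return(empty)
  tr[, rec_end := data.table::fifelse(concept == "resp_admission" &
                                        !is.na(discharge_date),
                                      discharge_date, date)]
  data.table::setorder(tr, patient_key, date, record_id)
  mw <- defn$merge_window_days
  tr[, episode := {
    gap_new <- rep(TRUE, .N)
    if (.N > 1L) {
      run_end <- as.integer(rec_end[1L])
      for (i in 2L:.N) {
        if (as.integer(date[i]) - run_end <= mw) {
          gap_new[i] <- FALSE
          run_end <- max(run_end, as.integer(rec_end[i]))
        } else {
          run_end <- as.integer(rec_end[i])
        }
      }
    }
    cumsum(gap_new)
  }, by = patient_key]
  tr[, .(start_date = min(date), end_date = as_idate(max(as.integer(rec_end))),
         severity = if (any(concept == "resp_admission")) "severe" else "moderate",
         n_records = .N,
         record_ids = paste(sort(record_id), collapse = ",")),
     by = .(patient_key, episode)][, episode := NULL][]
}

#' Follow-up person-time within an observation year
#'
#' Cohort exit is the earliest of death, deregistration (transfer out of
#' the registry) and the administrative end of the window. Time is
#' half-open: a patient followed for the whole default window contributes
#' 365/365.25 person-years; a patient dying on day *d* contributes *d*
#' days (the death date itself is not counted).
#'
#' @param journal journal `data.table` (death and deregistration are read
#'   from their event codes).
#' @param patient_keys patients to follow.
#' @param window half-open follow-up window, default calendar 2009.
#' @param codelist the code list.
#' @return `data.table(patient_key, entry_date, exit_date, exit_reason,
#'   person_years)`; `exit_reason` is `death`, `deregistration` or
#'   `admin_end`; zero person-years (exit before entry) are kept and
#'   flagged by `exit_reason`.
#' @export
person_time <- function(journal, patient_keys,
                        window = c("2009-01-01", "2010-01-01"),
                        codelist = load_codelist()) {
  window <- as_window(window, "window")
  entry <- window[1L]
  fu <- data.table(patient_key = patient_keys)
  first_event <- function(cpt) {
    codes <- concept_codes(codelist, cpt)
    journal[patient_key %in% patient_keys & record_kind == "event" &
              code %in% codes, .(d = min(date)), by = patient_key]
  }
  dd <- first_event("death")
  rg <- first_event("deregistration")
  fu <- merge(fu, dd[, .(patient_key, death_date = d)], by = "patient_key", all.x = TRUE)
  fu <- merge(fu, rg[, .(patient_key, dereg_date = d)], by = "patient_key", all.x = TRUE)
  ## exclusive exit boundary: event date, or the window end for admin exit
  fu[, exit_boundary := as_idate(pmin(as.integer(death_date),
                                      as.integer(dereg_date),
                                      as.integer(window[2L]), na.rm = TRUE))]
  fu[, exit_reason := data.table::fifelse(
    !is.na(death_date) & death_date == exit_boundary, "death",
    data.table::fifelse(!is.na(dereg_date) & dereg_date == exit_boundary,
                        "deregistration", "admin_end"))]
  fu[, entry_date := entry]
  fu[, person_years := pmax(0, as.numeric(exit_boundary - entry)) / 365.25]
  fu[, exit_date := data.table::fifelse(exit_reason == "admin_end",
                                        exit_boundary - 1L, exit_boundary)]
  fu[, c("death_date", "dereg_date") := NULL]
  data.table::setorder(fu, patient_key)
  fu[]
}

#' Health-care resource-utilisation rates per 100 person-years
#'
#' Counts, for each stratum of a cohort, short courses of oral steroids,
#' antibiotic prescriptions, all-cause GP visits (one per patient-day),
#' all-cause and respiratory hospital admissions over each member's
#' follow-up, and divides by the stratum person-years. Patients with more
#' than `ocs_outlier_threshold` OCS prescriptions during the baseline
#' year are excluded — numerator and denominator — from the OCS row only,
#' as resource-use outliers.
#'
#' @param cohort an `emr_cohort`.
#' @param journal journal of the same extract the cohort was built from.
#' @param strata named list of patient-key vectors; defaults to the whole
#'   cohort as stratum `"total"`.
#' @param window half-open follow-up window (default calendar 2009).
#' @param codelist the code list.
#' @param ocs_short_course_max_days OCS scripts above this supply are
#'   maintenance, not short courses.
#' @param ocs_outlier_threshold baseline OCS script count above which a
#'   patient is excluded from the OCS row.
#' @param followup optional precomputed [person_time()] table.
#' @return a `rate_table` `data.table(stratum, outcome, n_patients,
#'   events, person_years, rate)` with `rate = 100 * events /
#'   person_years` (`NA`, flagged, when a stratum has no person-time).
#' @export
hru_rates <- function(cohort, journal, strata = NULL,
                      window = c("2009-01-01", "2010-01-01"),
                      codelist = load_codelist(),
                      ocs_short_course_max_days = 21L,
                      ocs_outlier_threshold = 12L,
                      followup = NULL) {
  stopifnot(inherits(cohort, "emr_cohort"))
  window <- as_window(window, "window")
  keys <- cohort$members$patient_key
  if (is.null(strata)) strata <- list(total = keys)
  if (is.null(followup)) {
    followup <- person_time(journal, keys, window = window, codelist = codelist)
  }
  cpt_of <- stats::setNames(codelist$concept, codelist$code)
  jr <- journal[patient_key %in% keys]
  jr[, concept := cpt_of[code]]
  fu <- followup[, .(patient_key, entry_date,
                     boundary = entry_date + as.integer(round(person_years * 365.25)))]
  jr <- merge(jr, fu, by = "patient_key")
  jr <- jr[date >= entry_date & date < boundary]  # within follow-up

  ## baseline OCS outliers (counted over the baseline year of the spec)
  bwin <- cohort$spec$baseline_year_window
  ocs_base <- journal[patient_key %in% keys & record_kind == "prescription" &
                        cpt_of[code] == "ocs" & in_window(date, bwin),
                      .N, by = patient_key]
  ocs_outliers <- ocs_base[N > ocs_outlier_threshold, patient_key]

  count_events <- function(sub, what) {
    switch(what,
      ocs_short = sub[record_kind == "prescription" & concept == "ocs" &
                        (is.na(days_supply) |
                           days_supply <= ocs_short_course_max_days), .N],
      antibiotics = sub[record_kind == "prescription" & concept == "antibiotic", .N],
      gp_visits = sub[record_kind == "event" & concept == "gp_visit",
                      data.table::uniqueN(paste(patient_key, date))],
      hosp_all = sub[record_kind == "event" &
                       concept %in% c("resp_admission", "nonresp_admission"), .N],
      hosp_resp = sub[record_kind == "event" & concept == "resp_admission", .N])
  }
  outcomes <- c("ocs_short", "antibiotics", "gp_visits", "hosp_all", "hosp_resp")
  out <- list()
  for (s in names(strata)) {
    skeys <- intersect(strata[[s]], keys)
    for (oc in outcomes) {
      use <- if (oc == "ocs_short") setdiff(skeys, ocs_outliers) else skeys
      py <- followup[patient_key %in% use, sum(person_years)]
      ev <- count_events(jr[patient_key %in% use], oc)
      out[[length(out) + 1L]] <- data.table(
        stratum = s, outcome = oc, n_patients = length(use),
        events = as.numeric(ev), person_years = py,
        rate = if (py > 0) 100 * ev / py else NA_real_)
    }
  }
  res <- data.table::rbindlist(out)
  data.table::setattr(res, "class", c("rate_table", class(res)))
  res[]
}

#' Stratify a cohort by baseline exacerbation frequency
#'
#' Partitions members into infrequent (<= 1 baseline exacerbation
#' episode) and frequent (>= 2) exacerbators, and builds the maintenance
#' medication subset (asthma: any ICS, mono or combination; COPD:
#' ICS/LABA, LABA or LAMA).
#'
#' @param cohort an `emr_cohort` with `baseline_exacerbation_count`.
#' @return named list of patient-key vectors: `total`, `exac_le1`,
#'   `exac_ge2`, `med_subset`.
#' @export
stratify_by_baseline_exacerbations <- function(cohort) {
  stopifnot(inherits(cohort, "emr_cohort"))
  m <- cohort$members
  med <- if (cohort$disease == "asthma") {
    m[ics_mono | ics_laba, patient_key]
  } else {
    m[ics_laba | laba | lama, patient_key]
  }
  list(total = m$patient_key,
       exac_le1 = m[baseline_exacerbation_count <= 1L, patient_key],
       exac_ge2 = m[baseline_exacerbation_count >= 2L, patient_key],
       med_subset = med)
}

#' Hospital-days summary over follow-up
#'
#' Sums inpatient days within each member's follow-up (stays are clipped
#' at entry and exit) and reports mean days per patient per year and the
#' share of days due to respiratory admissions.
#'
#' @param cohort an `emr_cohort`.
#' @param journal journal of the same extract.
#' @param window half-open follow-up window.
#' @param codelist the code list.
#' @param followup optional precomputed [person_time()] table.
#' @return list with `total_days`, `resp_days`, `person_years`,
#'   `mean_days_per_patient_year`, `resp_share`.
#' @export
hospital_days_summary <- function(cohort, journal,
                                  window = c("2009-01-01", "2010-01-01"),
                                  codelist = load_codelist(),
                                  followup = NULL) {
  stopifnot(inherits(cohort, "emr_cohort"))
  window <- as_window(window, "window")
  keys <- cohort$members$patient_key
  if (is.null(followup)) {
    followup <- person_time(journal, keys, window = window, codelist = codelist)
  }
  cpt_of <- stats::setNames(codelist$concept, codelist$code)
  adm <- journal[patient_key %in% keys & record_kind == "event" &
                   cpt_of[code] %in% c("resp_admission", "nonresp_admission")]
  if (nrow(adm)) {
    if (any(!is.na(adm$discharge_date) & adm$discharge_date < adm$date)) {
      stop("admission with discharge_date before admission date", call. = FALSE)
    }
    adm[, resp := cpt_of[code] == "resp_admission"]
    fu <- followup[, .(patient_key, entry_date,
                       boundary = entry_date + as.integer(round(person_years * 365.25)))]
    adm <- merge(adm, fu, by = "patient_key")
    adm[, days := pmax(0, as.integer(pmin(as.integer(data.table::fifelse(
      is.na(discharge_date), date, discharge_date)), as.integer(boundary)) -
        pmax(as.integer(date), as.integer(entry_date))))]
    total_days <- adm[, sum(days)]
    resp_days <- adm[resp == TRUE, sum(days)]
  } else {
    total_days <- 0L
    resp_days <- 0L
  }
  py <- followup[, sum(person_years)]
  list(total_days = as.numeric(total_days), resp_days = as.numeric(resp_days),
       person_years = py,
       mean_days_per_patient_year = if (py > 0) total_days / py else NA_real_,
       resp_share = if (total_days > 0) resp_days / total_days else NA_real_)
}
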