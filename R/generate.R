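#' Parameters for the synthetic EMR population generator
#'
#' Defines the study conditions the generator emulates: an adult
#' primary-care population with coded asthma and COPD, class-coded
#' respiratory prescribing, treated exacerbations from a two-class
#' (frequent/infrequent) Poisson mixture, GP visits, hospitalisations with
#' lengths of stay, and deaths/deregistrations. Defaults are calibrated
#' once to the magnitudes a large UK primary-care registry reports for
#' these quantities; see the methods vignette for the provenance of each
#' default.
#'
#' @param n_adults number of adults (>= 1).
#' @param sex_fraction_male proportion male.
#' @param asthma_prevalence probability of a coded asthma diagnosis among
#'   adults without COPD.
#' @param copd_prevalence probability of a coded COPD diagnosis among
#'   adults aged >= 40 (COPD is not generated below 40).
#' @param comorbid_asthma_given_copd probability a COPD patient also
#'   carries an asthma diagnosis.
#' @param age_distribution list `(mean, sd, min, max)` for the truncated
#'   normal age distribution (years at `age_reference_date`).
#' @param prescribing_probabilities list with elements `asthma` and
#'   `copd`, each a named vector of per-class prescribing probabilities
#'   over `saba`, `laba`, `lama`, `ltra`, `ics`, `ics_laba`.
#' @param scripts_per_year expected repeat prescriptions per year for each
#'   prescribed class.
#' @param ocs_maintenance_prob named vector (`asthma`, `copd`): probability
#'   of maintenance oral corticosteroid therapy (28-day scripts issued
#'   monthly).
#' @param exac_rate_frequent,exac_rate_infrequent treated-exacerbation
#'   rates (events per person-year) for the frequent and infrequent
#'   exacerbator classes.
#' @param frequent_fraction proportion of diseased patients in the
#'   frequent-exacerbator class.
#' @param exac_severe_fraction proportion of exacerbations accompanied by
#'   a respiratory hospitalisation.
#' @param gp_visit_rate GP visits per person-year (all adults).
#' @param hosp_rate_allcause all-cause admissions per person-year
#'   (includes the respiratory component).
#' @param hosp_rate_respiratory background respiratory admissions per
#'   person-year (exacerbation-driven admissions are generated on top).
#' @param los_distribution list `(meanlog, sdlog)` of the log-normal
#'   length-of-stay distribution (days, rounded up, >= 1).
#' @param death_hazard,transfer_hazard exponential hazards per year for
#'   death and deregistration (transfer out of the registry).
#' @param study_window half-open `[start, end)` pair of ISO dates covered
#'   by prescriptions, visits and outcome events.
#' @param age_reference_date date at which the patient-file age is stated.
#' @param seed integer seed; identical parameters and seed reproduce the
#'   population exactly.
#' @return a validated `generator_params` list.
#' @export
generator_params <- function(n_adults = 10000L,
                             sex_fraction_male = 0.5025,
                             asthma_prevalence = 0.044,
                             copd_prevalence = 0.041,
                             comorbid_asthma_given_copd = 0.38,
                             age_distribution = list(mean = 49, sd = 18,
                                                     min = 18, max = 95),
                             prescribing_probabilities = list(
                               asthma = c(saba = 0.94, laba = 0.10, lama = 0.01,
                                          ltra = 0.04, ics = 0.42, ics_laba = 0.40),
                               copd = c(saba = 0.94, laba = 0.12, lama = 0.36,
                                        ltra = 0.03, ics = 0.15, ics_laba = 0.55)),
                             scripts_per_year = 8,
                             ocs_maintenance_prob = c(asthma = 0.02, copd = 0.05),
                             exac_rate_frequent = 1.4,
                             exac_rate_infrequent = 0.2,
                             frequent_fraction = 0.06,
                             exac_severe_fraction = 0.05,
                             gp_visit_rate = 10.7,
                             hosp_rate_allcause = 0.30,
                             hosp_rate_respiratory = 0.03,
                             los_distribution = list(meanlog = 1.2, sdlog = 0.8),
                             death_hazard = 0.01,
                             transfer_hazard = 0.02,
                             study_window = c("2007-01-01", "2010-01-01"),
                             age_reference_date = "2008-12-31",
                             seed = 1L) {
  p <- list(
    n_adults = check_count(n_adults, "n_adults", min = 1L),
    sex_fraction_male = sex_fraction_male,
    asthma_prevalence = asthma_prevalence,
    copd_prevalence = copd_prevalence,
    comorbid_asthma_given_copd = comorbid_asthma_given_copd,
    age_distribution = age_distribution,
    prescribing_probabilities = prescribing_probabilities,
    scripts_per_year = scripts_per_year,
    ocs_maintenance_prob = ocs_maintenance_prob,
    exac_rate_frequent = exac_rate_frequent,
    exac_rate_infrequent = exac_rate_infrequent,
    frequent_fraction = frequent_fraction,
    exac_severe_fraction = exac_severe_fraction,
    gp_visit_rate = gp_visit_rate,
    hosp_rate_allcause = hosp_rate_allcause,
    hosp_rate_respiratory = hosp_rate_respiratory,
    los_distribution = los_distribution,
    death_hazard = death_hazard,
    transfer_hazard = transfer_hazard,
    study_window = as_window(study_window, "study_window"),
    age_reference_date = as_idate(age_reference_date),
    seed = check_count(seed, "seed")
  )
  check_prob(p$sex_fraction_male, "sex_fraction_male")
  check_prob(p$asthma_prevalence, "asthma_prevalence")
  check_prob(p$copd_prevalence, "copd_prevalence")
  check_prob(p$comorbid_asthma_given_copd, "comorbid_asthma_given_copd")
  check_prob(p$frequent_fraction, "frequent_fraction")
  check_prob(p$exac_severe_fraction, "exac_severe_fraction")
  check_prob(p$ocs_maintenance_prob, "ocs_maintenance_prob")
  for (grp in c("asthma", "copd")) {
    pr <- p$prescribing_probabilities[[grp]]
    if (is.null(pr)) stop(sprintf("prescribing_probabilities$%s missing", grp), call. = FALSE)
    check_prob(pr, sprintf("prescribing_probabilities$%s", grp))
  }
  check_rate(p$scripts_per_year, "scripts_per_year")
  check_rate(p$exac_rate_frequent, "exac_rate_frequent")
  check_rate(p$exac_rate_infrequent, "exac_rate_infrequent")
  check_rate(p$gp_visit_rate, "gp_visit_rate")
  check_rate(p$hosp_rate_allcause, "hosp_rate_allcause")
  check_rate(p$hosp_rate_respiratory, "hosp_rate_respiratory")
  check_rate(p$death_hazard, "death_hazard")
  check_rate(p$transfer_hazard, "transfer_hazard")
  ad <- p$age_distribution
  if (!all(c("mean", "sd", "min", "max") %in% names(ad)) || ad$min >= ad$max || ad$min < 0) {
    stop("age_distribution needs mean, sd and 0 <= min < max", call. = FALSE)
  }
  structure(p, class = "generator_params")
}

## Truncated-normal sample by rejection; integer years.
rtnorm_age <- function(n, ad) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(max(n, 100L), ad$mean, ad$sd)
    out <- c(out, x[x >= ad$min & x <= ad$max])
  }
  floor(out[seq_len(n)])
}

## Expand per-patient Poisson counts into uniformly dated rows.
## ids: patient ids; exposure_days: per-patient days at risk (>= 0);
## rate: events per person-year. Returns data.table(person_id, date).
poisson_dates <- function(ids, start, exposure_days, rate) {
  lambda <- rate * exposure_days / 365.25
  n <- stats::rpois(length(ids), lambda)
  if (sum(n) == 0L) {
    return(data.table(person_id = integer(0), date = as_idate(character(0))))
  }
  pid <- rep(ids, n)
  span <- rep(exposure_days, n)
  data.table(person_id = pid,
             date = start + as.integer(floor(stats::runif(length(pid)) * span)))
}

sample_codes <- function(codelist, cpt, n) {
  codes <- codelist[concept == cpt, code]
  codes[sample.int(length(codes), n, replace = TRUE)]
}

empty_journal <- function() {
  data.table(person_id = integer(0), record_kind = character(0),
             code = character(0), date = as_idate(character(0)),
             quantity = numeric(0), daily_dose = numeric(0),
             days_supply = integer(0), value = numeric(0),
             discharge_date = as_idate(character(0)))
}

journal_rows <- function(person_id, record_kind, code, date,
                         quantity = NA_real_, daily_dose = NA_real_,
                         days_supply = NA_integer_, value = NA_real_,
                         discharge_date = as_idate(NA)) {
  data.table(person_id = as.integer(person_id), record_kind = record_kind,
             code = code, date = as_idate(date),
             quantity = as.numeric(quantity), daily_dose = as.numeric(daily_dose),
             days_supply = as.integer(days_supply), value = as.numeric(value),
             discharge_date = as_idate(discharge_date))
}

#' Generate a ground-truth EMR population
#'
#' Simulates the registry that two source extracts are later derived from:
#' patients with demographics, disease labels, exacerbator class and
#' death/deregistration dates, plus a journal of prescription and event
#' records. Every journal record respects the patient's exit date, so the
#' truth is internally consistent before any corruption is applied.
#'
#' @param params a [generator_params()] object.
#' @param codelist code list as returned by [load_codelist()].
#' @return an object of class `emr_truth`: a list with `patients`
#'   (one row per person: `person_id`, `sex`, `birth_date`, `death_date`,
#'   `transfer_date`, `asthma`, `copd`, `exac_class`, `age`), `journal`
#'   (see [read_extract()] for the record schema, plus `person_id` and
#'   `record_id`), and `params`.
#' @export
#' @examples
#' truth <- generate_population(generator_params(n_adults = 200, seed = 7))
#' truth$patients[, .N, by = .(asthma, copd)]
generate_population <- function(params, codelist = load_codelist()) {
  if (!inherits(params, "generator_params")) params <- do.call(generator_params, params)
  with_seed(params$seed, generate_population_impl(params, codelist))
}

generate_population_impl <- function(p, codelist) {
  n <- p$n_adults
  w0 <- p$study_window[1L]
  w1 <- p$study_window[2L]
  span_days <- as.integer(w1 - w0)

  sex <- ifelse(stats::runif(n) < p$sex_fraction_male, "M", "F")
  age <- rtnorm_age(n, p$age_distribution)
  ## birth date consistent with integer age at the reference date
  birth_date <- p$age_reference_date -
    as.integer(floor(age * 365.25) + floor(stats::runif(n) * 365))
  age <- as.integer(floor(as.numeric(p$age_reference_date - birth_date) / 365.25))

  copd <- age >= 40L & stats::runif(n) < p$copd_prevalence
  asthma <- ifelse(copd,
                   stats::runif(n) < p$comorbid_asthma_given_copd,
                   stats::runif(n) < p$asthma_prevalence)
  diseased <- asthma | copd

  ## competing exponential exit times from study start
  t_death <- if (p$death_hazard > 0) stats::rexp(n, p$death_hazard) * 365.25 else rep(Inf, n)
  t_xfer <- if (p$transfer_hazard > 0) stats::rexp(n, p$transfer_hazard) * 365.25 else rep(Inf, n)
  death_date <- as_idate(ifelse(t_death < span_days & t_death <= t_xfer,
                                as.integer(w0) + floor(t_death), NA))
  transfer_date <- as_idate(ifelse(t_xfer < span_days & t_xfer < t_death,
                                   as.integer(w0) + floor(t_xfer), NA))
  exit_date <- as_idate(pmin(as.integer(death_date), as.integer(transfer_date),
                             as.integer(w1), na.rm = TRUE))
  exposure <- as.numeric(exit_date - w0)  # days at risk within the window

  exac_class <- rep(NA_character_, n)
  exac_class[diseased] <- ifelse(stats::runif(sum(diseased)) < p$frequent_fraction,
                                 "frequent", "infrequent")

  patients <- data.table(
    person_id = seq_len(n), sex = sex, birth_date = birth_date,
    death_date = death_date, transfer_date = transfer_date,
    asthma = asthma, copd = copd, exac_class = exac_class, age = age)

  journal <- list()
  add <- function(x) journal[[length(journal) + 1L]] <<- x

  ## --- diagnoses (history can predate the study window) ---------------
  hist0 <- as_idate("1998-01-01")
  dx_hi <- pmin(exit_date, as_idate("2009-01-01"))
  for (dz in c("asthma", "copd")) {
    idx <- which(if (dz == "asthma") asthma else copd)
    if (!length(idx)) next
    span <- pmax(1L, as.integer(dx_hi[idx] - hist0))
    add(journal_rows(idx, "event",
                     sample_codes(codelist, paste0(dz, "_dx"), length(idx)),
                     hist0 + as.integer(floor(stats::runif(length(idx)) * span))))
  }

  ## --- rare exclusion diagnoses, any adult ------------------------------
  excl <- c(cystic_fibrosis_dx = 0.0002, lung_cancer_dx = 0.002,
            bronchiectasis_dx = 0.002, fibrotic_lung_dx = 0.001)
  for (cpt in names(excl)) {
    idx <- which(stats::runif(n) < excl[[cpt]] & exposure > 0)
    if (!length(idx)) next
    add(journal_rows(idx, "event", sample_codes(codelist, cpt, length(idx)),
                     w0 + as.integer(floor(stats::runif(length(idx)) * exposure[idx]))))
  }

  ## --- cardiovascular comorbidities -------------------------------------
  cv <- list(asthma = c(mi_dx = 0.03, hypertension_dx = 0.25,
                        stroke_dx = 0.01, heart_failure_dx = 0.02),
             copd = c(mi_dx = 0.11, hypertension_dx = 0.50,
                      stroke_dx = 0.05, heart_failure_dx = 0.10),
             none = c(mi_dx = 0.02, hypertension_dx = 0.15,
                      stroke_dx = 0.01, heart_failure_dx = 0.01))
  grp <- ifelse(copd, "copd", ifelse(asthma, "asthma", "none"))
  for (cpt in names(cv$copd)) {
    pr <- vapply(grp, function(g) cv[[g]][[cpt]], numeric(1))
    idx <- which(stats::runif(n) < pr)
    if (!length(idx)) next
    hi <- pmin(exit_date[idx], as_idate("2010-01-01"))
    span <- pmax(1L, as.integer(hi - hist0))
    add(journal_rows(idx, "event", sample_codes(codelist, cpt, length(idx)),
                     hist0 + as.integer(floor(stats::runif(length(idx)) * span))))
  }

  ## --- maintenance prescriptions by class -------------------------------
  for (dz in c("asthma", "copd")) {
    ## comorbid patients prescribe per their dominant label: COPD wins
    idx <- which(if (dz == "copd") copd else (asthma & !copd))
    if (!length(idx)) next
    probs <- p$prescribing_probabilities[[dz]]
    for (cls in names(probs)) {
      on_cls <- idx[stats::runif(length(idx)) < probs[[cls]] & exposure[idx] > 0]
      if (!length(on_cls)) next
      ev <- poisson_dates(on_cls, w0, exposure[on_cls], p$scripts_per_year)
      if (!nrow(ev)) next
      add(journal_rows(ev$person_id, "prescription",
                       sample_codes(codelist, cls, nrow(ev)), ev$date,
                       quantity = 1, daily_dose = sample(1:2, nrow(ev), TRUE),
                       days_supply = 28L))
    }
    ## maintenance OCS: monthly 28-day scripts
    m_idx <- idx[stats::runif(length(idx)) < p$ocs_maintenance_prob[[dz]] & exposure[idx] > 0]
    for (i in m_idx) {
      dates <- seq(from = as.integer(w0), to = as.integer(exit_date[i]) - 1L, by = 28L)
      add(journal_rows(rep(i, length(dates)), "prescription",
                       sample_codes(codelist, "ocs", length(dates)),
                       as_idate(dates), quantity = 1, daily_dose = 1,
                       days_supply = 28L))
    }
  }

  ## --- treated exacerbations (two-class Poisson mixture) ----------------
  d_idx <- which(diseased & exposure > 0)
  if (length(d_idx)) {
    lam <- ifelse(exac_class[d_idx] == "frequent",
                  p$exac_rate_frequent, p$exac_rate_infrequent)
    cnt <- stats::rpois(length(d_idx), lam * exposure[d_idx] / 365.25)
    if (sum(cnt)) {
      pid <- rep(d_idx, cnt)
      span <- rep(exposure[d_idx], cnt)
      edate <- w0 + as.integer(floor(stats::runif(length(pid)) * span))
      is_copd <- copd[pid]
      ## asthma exacerbations: always one short OCS course
      ## COPD exacerbations: OCS and/or antibiotic course (at least one)
      give_ocs <- !is_copd | stats::runif(length(pid)) < 0.5
      give_abx <- is_copd & stats::runif(length(pid)) < 0.8
      give_abx <- give_abx | (is_copd & !give_ocs & !give_abx)
      if (any(give_ocs)) {
        k <- sum(give_ocs)
        add(journal_rows(pid[give_ocs], "prescription",
                         sample_codes(codelist, "ocs", k), edate[give_ocs],
                         quantity = 1, daily_dose = 1,
                         days_supply = sample(5:7, k, TRUE)))
      }
      if (any(give_abx)) {
        k <- sum(give_abx)
        add(journal_rows(pid[give_abx], "prescription",
                         sample_codes(codelist, "antibiotic", k), edate[give_abx],
                         quantity = 1, daily_dose = 2,
                         days_supply = sample(5:7, k, TRUE)))
      }
      severe <- stats::runif(length(pid)) < p$exac_severe_fraction
      if (any(severe)) {
        k <- sum(severe)
        los <- pmax(1L, as.integer(ceiling(
          stats::rlnorm(k, p$los_distribution$meanlog, p$los_distribution$sdlog))))
        adm <- edate[severe]
        dis <- as_idate(pmax(pmin(as.integer(adm) + los,
                                  as.integer(exit_date[pid[severe]])),
                             as.integer(adm)))
        add(journal_rows(pid[severe], "event",
                         sample_codes(codelist, "resp_admission", k), adm,
                         discharge_date = dis))
      }
    }
  }

  ## --- GP visits (all adults) -------------------------------------------
  alive <- which(exposure > 0)
  gp <- poisson_dates(alive, w0, exposure[alive], p$gp_visit_rate)
  if (nrow(gp)) {
    add(journal_rows(gp$person_id, "event",
                     sample_codes(codelist, "gp_visit", nrow(gp)), gp$date))
  }

  ## --- hospitalisations --------------------------------------------------
  hosp <- list(nonresp_admission = max(0, p$hosp_rate_allcause - p$hosp_rate_respiratory),
               resp_admission = p$hosp_rate_respiratory)
  for (cpt in names(hosp)) {
    if (hosp[[cpt]] <= 0) next
    ev <- poisson_dates(alive, w0, exposure[alive], hosp[[cpt]])
    if (!nrow(ev)) next
    los <- pmax(1L, as.integer(ceiling(
      stats::rlnorm(nrow(ev), p$los_distribution$meanlog, p$los_distribution$sdlog))))
    dis <- pmin(ev$date + los, exit_date[ev$person_id])
    dis <- pmax(dis, ev$date)
    add(journal_rows(ev$person_id, "event",
                     sample_codes(codelist, cpt, nrow(ev)), ev$date,
                     discharge_date = dis))
  }

  ## --- baseline measurements (2008, diseased patients) -------------------
  b0 <- as_idate("2008-01-01")
  b1 <- as_idate("2009-01-01")
  meas_window <- function(idx) {
    hi <- pmin(exit_date[idx], b1)
    ok <- hi > b0
    idx <- idx[ok]
    list(idx = idx,
         date = b0 + as.integer(floor(stats::runif(length(idx)) *
                                        as.integer(hi[ok] - b0))))
  }
  d_all <- which(diseased)
  spiro <- d_all[stats::runif(length(d_all)) < 0.8]
  mw <- meas_window(spiro)
  if (length(mw$idx)) {
    is_c <- copd[mw$idx]
    fev1 <- pmax(0.3, stats::rnorm(length(mw$idx),
                                   ifelse(is_c, 1.45, 2.42),
                                   ifelse(is_c, 0.60, 0.83)))
    fvp <- pmax(10, stats::rnorm(length(mw$idx),
                                 ifelse(is_c, 61.0, 86.0),
                                 ifelse(is_c, 19.7, 18.4)))
    add(journal_rows(mw$idx, "event", sample_codes(codelist, "fev1", length(mw$idx)),
                     mw$date, value = round(fev1, 2)))
    add(journal_rows(mw$idx, "event", sample_codes(codelist, "fev1_pct_pred", length(mw$idx)),
                     mw$date, value = round(fvp, 1)))
  }
  pef_idx <- which(asthma & !copd)
  pef_idx <- pef_idx[stats::runif(length(pef_idx)) < 0.8]
  mw <- meas_window(pef_idx)
  if (length(mw$idx)) {
    add(journal_rows(mw$idx, "event", sample_codes(codelist, "pef", length(mw$idx)),
                     mw$date, value = round(pmax(60, stats::rnorm(length(mw$idx), 393.7, 123.8)))))
  }
  smk_idx <- d_all[stats::runif(length(d_all)) < 0.9]
  mw <- meas_window(smk_idx)
  if (length(mw$idx)) {
    is_c <- copd[mw$idx]
    ## 1 = current, 2 = former, 3 = never
    u <- stats::runif(length(mw$idx))
    smk <- ifelse(is_c, ifelse(u < 0.40, 1, ifelse(u < 0.92, 2, 3)),
                  ifelse(u < 0.27, 1, ifelse(u < 0.59, 2, 3)))
    add(journal_rows(mw$idx, "event", sample_codes(codelist, "smoking_status", length(mw$idx)),
                     mw$date, value = smk))
  }
  bmi_idx <- d_all[stats::runif(length(d_all)) < 0.85]
  mw <- meas_window(bmi_idx)
  if (length(mw$idx)) {
    add(journal_rows(mw$idx, "event", sample_codes(codelist, "bmi", length(mw$idx)),
                     mw$date, value = round(pmin(55, pmax(14, stats::rnorm(length(mw$idx), 27, 5))), 1)))
  }

  ## --- administrative exits ----------------------------------------------
  if (any(!is.na(death_date))) {
    idx <- which(!is.na(death_date))
    add(journal_rows(idx, "event", sample_codes(codelist, "death", length(idx)),
                     death_date[idx]))
  }
  if (any(!is.na(transfer_date))) {
    idx <- which(!is.na(transfer_date))
    add(journal_rows(idx, "event", sample_codes(codelist, "deregistration", length(idx)),
                     transfer_date[idx]))
  }

  journal <- data.table::rbindlist(journal, use.names = TRUE)
  if (!nrow(journal)) journal <- empty_journal()
  data.table::setorder(journal, person_id, date, record_kind, code)
  journal[, record_id := seq_len(.N)]

  structure(list(patients = patients, journal = journal, params = p),
            class = "emr_truth")
}

#' @export
print.emr_truth <- function(x, ...) {
  cat(sprintf("<emr_truth> %d adults, %d journal records (%d prescriptions)\n",
              nrow(x$patients), nrow(x$journal),
              x$journal[record_kind == "prescription", .N]))
  cat(sprintf("  asthma %d | copd %d | window %s .. %s\n",
              sum(x$patients$asthma), sum(x$patients$copd),
              as.character(x$params$study_window[1L]),
              as.character(x$params$study_window[2L])))
  invisible(x)
}
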