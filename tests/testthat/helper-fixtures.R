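## Shared fixture builders. Everything is constructed in code at test time;
## no data files.

library(data.table)

CL <- emrcohort::load_codelist()

## Build a source_extract from compact row specs.
## patients: data.frame(patient_key, age, sex)
## journal rows: list of lists with fields patient_key, code, date and
## optional quantity, daily_dose, days_supply, value, discharge_date.
make_extract <- function(patients, journal = list(), source_name = "test") {
  pat <- data.table::as.data.table(patients)
  pat[, age := as.integer(age)]
  kind_of <- stats::setNames(CL$record_kind, CL$code)
  if (length(journal)) {
    jr <- data.table::rbindlist(lapply(journal, function(r) {
      data.table::data.table(
        patient_key = r$patient_key,
        record_kind = kind_of[[r$code]],
        code = r$code,
        date = data.table::as.IDate(r$date),
        quantity = as.numeric(r$quantity %||% NA),
        daily_dose = as.numeric(r$daily_dose %||% NA),
        days_supply = as.integer(r$days_supply %||% NA),
        value = as.numeric(r$value %||% NA),
        discharge_date = data.table::as.IDate(r$discharge_date %||% NA))
    }))
  } else {
    jr <- data.table::data.table(
      patient_key = character(0), record_kind = character(0),
      code = character(0), date = data.table::as.IDate(character(0)),
      quantity = numeric(0), daily_dose = numeric(0),
      days_supply = integer(0), value = numeric(0),
      discharge_date = data.table::as.IDate(character(0)))
  }
  data.table::setorder(jr, patient_key, date, record_kind, code)
  jr[, record_id := seq_len(.N)]
  structure(list(source_name = source_name, patients = pat, journal = jr),
            class = "source_extract")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rx <- function(patient_key, code, date, days_supply = 28L, quantity = 1) {
  list(patient_key = patient_key, code = code, date = date,
       quantity = quantity, days_supply = days_supply)
}
ev <- function(patient_key, code, date, value = NULL, discharge_date = NULL) {
  list(patient_key = patient_key, code = code, date = date,
       value = value, discharge_date = discharge_date)
}

## A deterministic two-source pair calibrated to the published concordance
## counts: registry_total persons of whom `in_neither` appear in no source,
## `only_a`/`only_b` in one source each; rx_total prescriptions and dx_total
## diagnosis records over the co-present patients; A lacks rx_miss_a
## prescriptions and B rx_miss_b; B additionally lacks dx_miss_b_bulk
## diagnosis records; the condition table for copd_dx is engineered to
## (both_pos, a_only, b_only) = (75, 1, 2).
make_calibrated_pair <- function(registry_total = 3504L, in_neither = 14L,
                                 only_a = 27L, only_b = 10L,
                                 rx_total = 94070L, rx_miss_a = 10L,
                                 rx_miss_b = 3L,
                                 dx_total = 29830L, dx_miss_b = 272L,
                                 copd_both = 75L, copd_a_only = 1L,
                                 copd_b_only = 2L) {
  keys <- sprintf("P%06d", seq_len(registry_total))
  set_neither <- keys[seq_len(in_neither)]
  set_a_only <- keys[in_neither + seq_len(only_a)]
  set_b_only <- keys[in_neither + only_a + seq_len(only_b)]
  set_both <- setdiff(keys, c(set_neither, set_a_only, set_b_only))

  n_both <- length(set_both)
  ## prescriptions: round-robin over co-present patients, distinct dates
  i <- seq_len(rx_total) - 1L
  rx_dt <- data.table(
    patient_key = set_both[(i %% n_both) + 1L],
    record_kind = "prescription", code = "SAB01",
    date = data.table::as.IDate("2008-01-01") + (i %/% n_both),
    quantity = 1, daily_dose = NA_real_, days_supply = 28L,
    value = NA_real_, discharge_date = data.table::as.IDate(NA))

  ## condition patients: first copd_both + copd_a_only + copd_b_only of set_both
  c_both <- set_both[seq_len(copd_both)]
  c_a <- set_both[copd_both + seq_len(copd_a_only)]
  c_b <- set_both[copd_both + copd_a_only + seq_len(copd_b_only)]
  copd_dt <- data.table(
    patient_key = c(c_both, c_a, c_b),
    record_kind = "event", code = "CPD01",
    date = data.table::as.IDate("2008-06-15"),
    quantity = NA_real_, daily_dose = NA_real_, days_supply = NA_integer_,
    value = NA_real_, discharge_date = data.table::as.IDate(NA))

  n_bulk <- dx_total - nrow(copd_dt)
  i <- seq_len(n_bulk) - 1L
  bulk_dt <- data.table(
    patient_key = set_both[(i %% n_both) + 1L],
    record_kind = "event", code = "AST01",
    date = data.table::as.IDate("2008-02-01") + (i %/% n_both),
    quantity = NA_real_, daily_dose = NA_real_, days_supply = NA_integer_,
    value = NA_real_, discharge_date = data.table::as.IDate(NA))

  build <- function(patient_keys, drop_rx_idx, drop_bulk_idx, copd_keys, name) {
    pat <- data.table(patient_key = sort(patient_keys), age = 50L, sex = "M")
    jr <- rbind(rx_dt[setdiff(seq_len(nrow(rx_dt)), drop_rx_idx)],
                copd_dt[patient_key %in% copd_keys],
                bulk_dt[setdiff(seq_len(nrow(bulk_dt)), drop_bulk_idx)])
    jr <- jr[patient_key %in% patient_keys]
    data.table::setorder(jr, patient_key, date, record_kind, code)
    jr[, record_id := seq_len(.N)]
    structure(list(source_name = name, patients = pat, journal = jr),
              class = "source_extract")
  }
  ## A (apollo-like) misses rx_miss_a prescriptions and the b-only condition
  ## records; B (sir-like) misses rx_miss_b prescriptions, dx_miss_b - 1 bulk
  ## diagnosis records plus the a-only condition record (so 272 in total).
  a <- build(c(set_both, set_a_only), drop_rx_idx = seq_len(rx_miss_a),
             drop_bulk_idx = integer(0), copd_keys = c(c_both, c_a), "apollo")
  b <- build(c(set_both, set_b_only),
             drop_rx_idx = rx_miss_a + seq_len(rx_miss_b),
             drop_bulk_idx = seq_len(dx_miss_b - 1L),
             copd_keys = c(c_both, c_b), "sir")
  list(a = a, b = b, registry_total = registry_total)
}

## A patient defined by which asthma-eligibility predicates hold; used by
## the rule unit tests and the exhaustive truth-table test.
eligibility_patient <- function(key, dx, rx2, adult, excl, ocs90, copd_codx) {
  journal <- list()
  if (dx) journal <- c(journal, list(ev(key, "AST01", "2008-05-01")))
  if (rx2) {
    journal <- c(journal, list(rx(key, "SAB01", "2008-02-01"),
                               rx(key, "SAB02", "2008-06-01")))
  } else {
    journal <- c(journal, list(rx(key, "SAB01", "2008-02-01")))
  }
  if (excl) journal <- c(journal, list(ev(key, "LCA01", "2008-09-01")))
  if (ocs90) {
    ## 95 consecutive days of OCS supply during 2008
    journal <- c(journal, list(rx(key, "OCS01", "2008-03-01", days_supply = 50),
                               rx(key, "OCS01", "2008-04-20", days_supply = 45)))
  }
  if (copd_codx) journal <- c(journal, list(ev(key, "CPD01", "2007-01-10")))
  list(patient = data.frame(patient_key = key, age = if (adult) 50L else 16L,
                            sex = "F"),
       journal = journal)
}

build_eligibility_extract <- function(flags) {
  parts <- lapply(seq_len(nrow(flags)), function(i) {
    f <- flags[i, ]
    eligibility_patient(f$key, f$dx, f$rx2, f$adult, f$excl, f$ocs90, f$copd_codx)
  })
  make_extract(do.call(rbind, lapply(parts, `[[`, "patient")),
               do.call(c, lapply(parts, `[[`, "journal")))
}
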