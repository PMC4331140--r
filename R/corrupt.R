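#' Corruption profile for deriving a source extract
#'
#' Describes how an extraction route degrades the ground truth: whole
#' patients silently missing, individual records dropped by kind, and
#' records duplicated. Magnitudes of a few per-mille emulate the record
#' discordance observed when two independent extraction routes are
#' compared against each other.
#'
#' @param drop_patient_prob probability a patient is absent from the
#'   extract entirely.
#' @param drop_record_prob named vector over `prescription` and `event`:
#'   probability each surviving record is lost.
#' @param duplicate_record_prob probability a surviving record appears
#'   twice.
#' @param seed integer seed for this source's corruption stream.
#' @return a validated `corruption_profile` list.
#' @export
corruption_profile <- function(drop_patient_prob = 0,
                               drop_record_prob = c(prescription = 0, event = 0),
                               duplicate_record_prob = 0,
                               seed = 1L) {
  if (is.null(names(drop_record_prob))) {
    drop_record_prob <- c(prescription = drop_record_prob[[1L]],
                          event = drop_record_prob[[length(drop_record_prob)]])
  }
  drop_record_prob <- c(prescription = drop_record_prob[["prescription"]] %||% 0,
                        event = drop_record_prob[["event"]] %||% 0)
  p <- list(drop_patient_prob = drop_patient_prob,
            drop_record_prob = drop_record_prob,
            duplicate_record_prob = duplicate_record_prob,
            seed = check_count(seed, "seed"))
  check_prob(p$drop_patient_prob, "drop_patient_prob")
  check_prob(p$drop_record_prob, "drop_record_prob")
  check_prob(p$duplicate_record_prob, "duplicate_record_prob")
  structure(p, class = "corruption_profile")
}

#' Derive a corrupted source extract from the ground truth
#'
#' Applies a [corruption_profile()] to an `emr_truth` object and rekeys
#' the surviving patients with source-specific pseudonyms, producing the
#' patient-file + journal-file pair one extraction route would deliver.
#' The pseudonym-to-person map is retained on the result (element
#' `key_map`) for use as a test oracle; it is never written by
#' [write_extract()].
#'
#' @param truth an `emr_truth` from [generate_population()].
#' @param profile a [corruption_profile()].
#' @param source_name short label, e.g. `"sir"` or `"apollo"`; embedded in
#'   the pseudonyms so two sources never share a key space by accident.
#' @return a `source_extract`: list with `source_name`, `patients`
#'   (`patient_key`, `age`, `sex`), `journal` (pseudonymised records with
#'   `record_id`), and `key_map`.
#' @export
corrupt_to_source <- function(truth, profile, source_name) {
  stopifnot(inherits(truth, "emr_truth"))
  if (!inherits(profile, "corruption_profile")) profile <- do.call(corruption_profile, profile)
  if (!is.character(source_name) || length(source_name) != 1L || !nzchar(source_name)) {
    stop("source_name must be a non-empty string", call. = FALSE)
  }
  with_seed(profile$seed, {
    pat <- data.table::copy(truth$patients)
    keep <- stats::runif(nrow(pat)) >= profile$drop_patient_prob
    pat <- pat[keep]

    ## source-specific pseudonyms in shuffled order
    perm <- sample.int(nrow(pat))
    key <- sprintf("%s-%06d", source_name, perm)
    key_map <- data.table(patient_key = key, person_id = pat$person_id)

    jr <- truth$journal[person_id %in% pat$person_id]
    if (nrow(jr)) {
      pdrop <- profile$drop_record_prob[jr$record_kind]
      jr <- jr[stats::runif(nrow(jr)) >= pdrop]
    }
    if (nrow(jr) && profile$duplicate_record_prob > 0) {
      dup <- jr[stats::runif(nrow(jr)) < profile$duplicate_record_prob]
      jr <- data.table::rbindlist(list(jr, dup))
    }
    jr <- merge(jr, key_map, by = "person_id", sort = FALSE)
    jr[, person_id := NULL]
    jr[, record_id := NULL]
    data.table::setcolorder(jr, c("patient_key", "record_kind", "code", "date",
                                  "quantity", "daily_dose", "days_supply",
                                  "value", "discharge_date"))
    data.table::setorder(jr, patient_key, date, record_kind, code)
    jr[, record_id := seq_len(.N)]

    patients <- data.table(patient_key = key, age = pat$age, sex = pat$sex)
    data.table::setorder(patients, patient_key)
    structure(list(source_name = source_name, patients = patients,
                   journal = jr, key_map = key_map),
              class = "source_extract")
  })
}

#' @export
print.source_extract <- function(x, ...) {
  cat(sprintf("<source_extract '%s'> %d patients, %d journal records\n",
              x$source_name, nrow(x$patients), nrow(x$journal)))
  invisible(x)
}
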