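## CSV interchange for source extracts.
##
## patients.csv: patient_key,age,sex            (sex in {M,F})
## journal.csv:  patient_key,record_kind,code,date,quantity,daily_dose,
##               days_supply,value,discharge_date
## Empty fields mean "not applicable"; dates are ISO-8601; UTF-8; header
## row mandatory.

JOURNAL_COLS <- c("patient_key", "record_kind", "code", "date", "quantity",
                  "daily_dose", "days_supply", "value", "discharge_date")

#' Write a source extract as a CSV file pair
#'
#' @param extract a `source_extract`.
#' @param directory output directory (created if absent); receives
#'   `patients.csv` and `journal.csv`.
#' @return the directory, invisibly.
#' @seealso [read_extract()] — the pair round-trips losslessly.
#' @export
write_extract <- function(extract, directory) {
  stopifnot(inherits(extract, "source_extract"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(directory)) {
      stop(sprintf("cannot create directory '%s'", directory), call. = FALSE)
    }
  }
  jr <- extract$journal[, .SD, .SDcols = JOURNAL_COLS]
  data.table::fwrite(extract$patients, file.path(directory, "patients.csv"), na = "")
  data.table::fwrite(jr, file.path(directory, "journal.csv"), na = "")
  invisible(directory)
}

parse_num <- function(x, col, rows) {
  out <- rep(NA_real_, length(x))
  has <- nzchar(x)
  out[has] <- suppressWarnings(as.numeric(x[has]))
  bad <- has & is.na(out)
  if (any(bad)) {
    stop(sprintf("journal.csv row %d: invalid %s '%s'",
                 rows[which(bad)[1L]], col, x[which(bad)[1L]]), call. = FALSE)
  }
  out
}

parse_date_col <- function(x, col, rows, file = "journal.csv") {
  out <- data.table::as.IDate(rep(NA_integer_, length(x)), origin = "1970-01-01")
  has <- nzchar(x)
  out[has] <- suppressWarnings(data.table::as.IDate(x[has], format = "%Y-%m-%d"))
  bad <- has & is.na(out)
  if (any(bad)) {
    stop(sprintf("%s row %d: invalid %s '%s'",
                 file, rows[which(bad)[1L]], col, x[which(bad)[1L]]), call. = FALSE)
  }
  out
}

#' Read and validate a source extract from a directory
#'
#' Parses `patients.csv` and `journal.csv`, checks every row against the
#' code list and the record invariants, and reports the first offending
#' row by number on failure. CRLF and LF files parse identically.
#'
#' @param directory directory holding the CSV pair.
#' @param codelist code list used to validate journal codes and their
#'   record kinds.
#' @param source_name label for the extract; defaults to the directory
#'   basename.
#' @return a `source_extract` (without a `key_map`).
#' @export
read_extract <- function(directory, codelist = load_codelist(),
                         source_name = basename(normalizePath(directory))) {
  pfile <- file.path(directory, "patients.csv")
  jfile <- file.path(directory, "journal.csv")
  for (f in c(pfile, jfile)) {
    if (!file.exists(f)) stop(sprintf("missing file: %s", f), call. = FALSE)
  }
  pat <- data.table::fread(pfile, colClasses = "character")
  if (!identical(names(pat), c("patient_key", "age", "sex"))) {
    stop("patients.csv must have header patient_key,age,sex", call. = FALSE)
  }
  if (nrow(pat)) {
    rows <- seq_len(nrow(pat)) + 1L  # header is line 1
    if (anyDuplicated(pat$patient_key)) {
      stop(sprintf("patients.csv row %d: duplicate patient_key '%s'",
                   rows[which(duplicated(pat$patient_key))[1L]],
                   pat$patient_key[which(duplicated(pat$patient_key))[1L]]),
           call. = FALSE)
    }
    bad <- !pat$sex %in% c("M", "F")
    if (any(bad)) {
      stop(sprintf("patients.csv row %d: sex must be M or F, got '%s'",
                   rows[which(bad)[1L]], pat$sex[which(bad)[1L]]), call. = FALSE)
    }
    age_int <- suppressWarnings(as.integer(pat$age))
    bad <- is.na(age_int) | age_int < 0
    if (any(bad)) {
      stop(sprintf("patients.csv row %d: invalid age '%s'",
                   rows[which(bad)[1L]], pat$age[which(bad)[1L]]), call. = FALSE)
    }
    pat[, age := age_int]
  } else {
    pat[, age := integer(0)]
  }

  jr <- data.table::fread(jfile, colClasses = "character")
  if (!identical(names(jr), JOURNAL_COLS)) {
    stop(sprintf("journal.csv must have header %s",
                 paste(JOURNAL_COLS, collapse = ",")), call. = FALSE)
  }
  if (nrow(jr)) {
    rows <- seq_len(nrow(jr)) + 1L
    bad <- !jr$record_kind %in% c("prescription", "event")
    if (any(bad)) {
      stop(sprintf("journal.csv row %d: unknown record_kind '%s'",
                   rows[which(bad)[1L]], jr$record_kind[which(bad)[1L]]), call. = FALSE)
    }
    known <- jr$code %in% codelist$code
    if (!all(known)) {
      stop(sprintf("journal.csv row %d: unknown code '%s'",
                   rows[which(!known)[1L]], jr$code[which(!known)[1L]]), call. = FALSE)
    }
    kind_of <- stats::setNames(codelist$record_kind, codelist$code)
    bad <- kind_of[jr$code] != jr$record_kind
    if (any(bad)) {
      stop(sprintf("journal.csv row %d: code '%s' is a %s code but record_kind is '%s'",
                   rows[which(bad)[1L]], jr$code[which(bad)[1L]],
                   kind_of[jr$code[which(bad)[1L]]], jr$record_kind[which(bad)[1L]]),
           call. = FALSE)
    }
    orphan <- !jr$patient_key %in% pat$patient_key
    if (any(orphan)) {
      stop(sprintf("journal.csv row %d: patient_key '%s' not in patients.csv",
                   rows[which(orphan)[1L]], jr$patient_key[which(orphan)[1L]]),
           call. = FALSE)
    }
    jr[, date := parse_date_col(jr$date, "date", rows)]
    if (anyNA(jr$date)) {
      stop(sprintf("journal.csv row %d: date is required",
                   rows[which(is.na(jr$date))[1L]]), call. = FALSE)
    }
    jr[, quantity := parse_num(quantity, "quantity", rows)]
    jr[, daily_dose := parse_num(daily_dose, "daily_dose", rows)]
    ds <- parse_num(jr$days_supply, "days_supply", rows)
    bad <- !is.na(ds) & ds < 1
    if (any(bad)) {
      stop(sprintf("journal.csv row %d: days_supply must be >= 1",
                   rows[which(bad)[1L]]), call. = FALSE)
    }
    jr[, days_supply := as.integer(ds)]
    jr[, value := parse_num(value, "value", rows)]
    jr[, discharge_date := parse_date_col(jr$discharge_date, "discharge_date", rows)]
    bad <- !is.na(jr$discharge_date) & jr$discharge_date < jr$date
    if (any(bad)) {
      stop(sprintf("journal.csv row %d: discharge_date before date",
                   rows[which(bad)[1L]]), call. = FALSE)
    }
  } else {
    jr <- empty_journal()[, person_id := NULL]
    jr[, patient_key := character(0)]
    data.table::setcolorder(jr, JOURNAL_COLS)
  }
  jr[, record_id := seq_len(.N)]
  structure(list(source_name = source_name, patients = pat, journal = jr),
            class = "source_extract")
}

## structural invariants shared by generated and read extracts
validate_extract <- function(x, what = "extract") {
  stopifnot(inherits(x, "source_extract"))
  if (anyDuplicated(x$patients$patient_key)) {
    stop(sprintf("%s: duplicate patient_key in patient file", what), call. = FALSE)
  }
  if (nrow(x$journal) && !all(x$journal$patient_key %in% x$patients$patient_key)) {
    stop(sprintf("%s: journal references unknown patient_key", what), call. = FALSE)
  }
  invisible(x)
}
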