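#' Load the packaged clinical code list
#'
#' The package ships a simplified code list of ~60 synthetic codes grouped
#' into clinical concepts (diagnoses, medication classes, visits,
#' admissions, measurements, administrative events). It stands in for the
#' hierarchical Read-code dictionary used in UK primary care, which is
#' licensed and irrelevant to the phenotyping logic: every rule in this
#' package operates on concepts, never on raw codes.
#'
#' @param path optional path to an alternative code-list CSV with columns
#'   `code,concept,record_kind,class`.
#' @return a `data.table` with columns `code`, `concept`, `record_kind`
#'   (`"prescription"` or `"event"`) and `class` (medication class for
#'   prescriptions, `""` otherwise).
#' @export
#' @examples
#' cl <- load_codelist()
#' cl[concept == "copd_dx"]
load_codelist <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "codelist.csv", package = "emrcohort")
  }
  if (!file.exists(path)) stop(sprintf("code list not found: %s", path), call. = FALSE)
  cl <- data.table::fread(path, colClasses = "character")
  need <- c("code", "concept", "record_kind", "class")
  if (!all(need %in% names(cl))) {
    stop("code list must have columns code,concept,record_kind,class", call. = FALSE)
  }
  if (anyDuplicated(cl$code)) stop("duplicate codes in code list", call. = FALSE)
  if (!all(cl$record_kind %in% c("prescription", "event"))) {
    stop("record_kind must be 'prescription' or 'event'", call. = FALSE)
  }
  cl[]
}

## codes for one or more concepts; errors on unknown concept
concept_codes <- function(codelist, concepts) {
  unknown <- setdiff(concepts, unique(codelist$concept))
  if (length(unknown)) {
    stop(sprintf("unknown concept(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  codelist[concept %in% concepts, code]
}

## diagnosis concepts are those named *_dx
diagnosis_concepts <- function(codelist) {
  unique(grep("_dx$", codelist$concept, value = TRUE))
}

## Concepts counted as inhaled bronchodilators for eligibility. Combination
## ICS/LABA products contain a long-acting bronchodilator and count.
bronchodilator_concepts <- function() c("saba", "laba", "lama", "ics_laba")
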