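#' Define a rule for the event alert engine
#'
#' A rule names the clinical concepts it watches and fires when a
#' patient's records satisfy the predicate: optionally a value threshold
#' (for measurement events) and optionally a minimum record count inside
#' a sliding day window. Records outside the rule's active window are
#' never considered.
#'
#' @param rule_id unique identifier.
#' @param concepts code-list concepts watched.
#' @param value_op,value_threshold optional comparator (`">"`, `">="`,
#'   `"<"`, `"<="`, `"=="`) and threshold applied to the record `value`.
#' @param min_count minimum number of qualifying records (>= 1).
#' @param window_days sliding window for `min_count` > 1; `NULL` means
#'   unbounded.
#' @param scope `"all"` or a character vector of patient keys.
#' @param active_window half-open date window the rule applies to.
#' @return an `alert_rule` list.
#' @export
alert_rule <- function(rule_id, concepts, value_op = NULL,
                       value_threshold = NULL, min_count = 1L,
                       window_days = NULL, scope = "all",
                       active_window = c("1900-01-01", "2100-01-01")) {
  if (!is.character(rule_id) || length(rule_id) != 1L || !nzchar(rule_id)) {
    stop("rule_id must be a non-empty string", call. = FALSE)
  }
  if (!length(concepts)) stop("rule needs at least one concept", call. = FALSE)
  if (!is.null(value_op) &&
      !value_op %in% c(">", ">=", "<", "<=", "==")) {
    stop("value_op must be one of > >= < <= ==", call. = FALSE)
  }
  structure(list(rule_id = rule_id, concepts = concepts,
                 value_op = value_op, value_threshold = value_threshold,
                 min_count = check_count(min_count, "min_count", min = 1L),
                 window_days = if (is.null(window_days)) NULL else
                   check_count(window_days, "window_days", min = 1L),
                 scope = scope,
                 active_window = as_window(active_window, "active_window")),
            class = "alert_rule")
}

#' Create an alert engine over a rule set
#'
#' The engine retains state between daily batches: all ingested records
#' (deduplicated by record id) and all alerts already emitted, keyed by
#' (rule, patient, trigger set). Replaying an identical batch is a no-op.
#'
#' @param rules list of [alert_rule()] objects.
#' @param codelist the code list.
#' @return an `alert_engine` environment.
#' @export
alert_engine <- function(rules, codelist = load_codelist()) {
  if (inherits(rules, "alert_rule")) rules <- list(rules)
  stopifnot(all(vapply(rules, inherits, logical(1), "alert_rule")))
  ids <- vapply(rules, `[[`, character(1), "rule_id")
  if (anyDuplicated(ids)) stop("duplicate rule_id", call. = FALSE)
  e <- new.env(parent = emptyenv())
  e$rules <- stats::setNames(rules, ids)
  e$codelist <- codelist
  e$records <- NULL
  e$seen_keys <- character(0)
  e$alert_keys <- character(0)
  e$alerts <- data.table(rule_id = character(0), patient_key = character(0),
                         trigger_record_ids = character(0),
                         fire_date = as_idate(character(0)))
  class(e) <- "alert_engine"
  e
}

record_keys <- function(records) {
  paste(records$patient_key, records$record_id, sep = "#")
}

#' Ingest a daily batch of journal records
#'
#' Validates that no record is dated after the batch date, adds records
#' not seen before, evaluates every rule whose active window covers new
#' records, and returns the alerts newly emitted (also appended to the
#' engine's log). Idempotent under batch replay.
#'
#' @param engine an [alert_engine()].
#' @param records journal `data.table` with `record_id` (e.g. a slice of
#'   a source extract's journal).
#' @param batch_date the batch's download date.
#' @return `data.table` of new alerts: `rule_id`, `patient_key`,
#'   `trigger_record_ids` (comma-separated), `fire_date`.
#' @export
ingest_batch <- function(engine, records, batch_date) {
  stopifnot(inherits(engine, "alert_engine"))
  batch_date <- as_idate(batch_date)
  if (nrow(records) && any(records$date > batch_date)) {
    bad <- records[date > batch_date][1L]
    stop(sprintf("record %s dated %s is after batch_date %s",
                 bad$record_id, as.character(bad$date),
                 as.character(batch_date)), call. = FALSE)
  }
  new <- records[!record_keys(records) %in% engine$seen_keys]
  if (nrow(new)) {
    engine$records <- data.table::rbindlist(list(engine$records, new),
                                            use.names = TRUE, fill = TRUE)
    engine$seen_keys <- c(engine$seen_keys, record_keys(new))
  }
  cpt_of <- stats::setNames(engine$codelist$concept, engine$codelist$code)
  out <- list()
  for (rule in engine$rules) {
    if (!nrow(new)) break
    cand <- engine$records[cpt_of[code] %in% rule$concepts &
                             in_window(date, rule$active_window)]
    if (!is.null(rule$value_op)) {
      cand <- cand[!is.na(value) &
                     do.call(rule$value_op, list(value, rule$value_threshold))]
    }
    if (!identical(rule$scope, "all")) {
      cand <- cand[patient_key %in% rule$scope]
    }
    if (!nrow(cand)) next
    new_keys <- record_keys(new)
    cand[, is_new := record_keys(cand) %in% new_keys]
    touched <- cand[is_new == TRUE, unique(patient_key)]
    for (pk in touched) {
      pc <- cand[patient_key == pk][order(date, record_id)]
      trig <- NULL
      if (rule$min_count <= 1L) {
        ## one alert per new qualifying record
        trig <- lapply(pc[is_new == TRUE, record_id], identity)
      } else if (is.null(rule$window_days)) {
        if (nrow(pc) >= rule$min_count) trig <- list(pc$record_id)
      } else {
        ## sliding window ending at each new record
        for (i in which(pc$is_new)) {
          lo <- pc$date[i] - rule$window_days
          win <- pc[date > lo & date <= pc$date[i], record_id]
          if (length(win) >= rule$min_count) trig <- c(trig, list(win))
        }
      }
      for (ids in trig) {
        sig <- paste(sort(ids), collapse = ",")
        akey <- paste(rule$rule_id, pk, sig, sep = "|")
        if (akey %in% engine$alert_keys) next
        engine$alert_keys <- c(engine$alert_keys, akey)
        out[[length(out) + 1L]] <- data.table(
          rule_id = rule$rule_id, patient_key = pk,
          trigger_record_ids = sig, fire_date = batch_date)
      }
    }
  }
  new_alerts <- if (length(out)) data.table::rbindlist(out) else
    engine$alerts[0L]
  engine$alerts <- data.table::rbindlist(list(engine$alerts, new_alerts))
  new_alerts[]
}

#' Daily activity summary of emitted alerts
#'
#' @param engine an [alert_engine()].
#' @param date summary date.
#' @return `data.table(rule_id, n_alerts, patients)` for alerts fired on
#'   that date; `patients` is a comma-separated patient list.
#' @export
activity_summary <- function(engine, date) {
  stopifnot(inherits(engine, "alert_engine"))
  date <- as_idate(date)
  day <- engine$alerts[fire_date == date]
  day[, .(n_alerts = .N,
          patients = paste(sort(unique(patient_key)), collapse = ",")),
      by = rule_id]
}

#' @export
print.alert_engine <- function(x, ...) {
  cat(sprintf("<alert_engine> %d rules, %d records ingested, %d alerts emitted\n",
              length(x$rules), if (is.null(x$records)) 0L else nrow(x$records),
              nrow(x$alerts)))
  invisible(x)
}

#' Read alert rules from a YAML file
#'
#' The file holds a list under `rules:`, each entry with fields matching
#' the [alert_rule()] arguments (`id`, `concepts`, optional `value_op`,
#' `value_threshold`, `min_count`, `window_days`, `scope`, `active_from`,
#' `active_to`).
#'
#' @param path YAML file path.
#' @return list of [alert_rule()] objects.
#' @export
read_alert_rules <- function(path) {
  if (!file.exists(path)) stop(sprintf("rules file not found: %s", path), call. = FALSE)
  y <- yaml::read_yaml(path)
  rules <- y$rules %||% y
  lapply(rules, function(r) {
    alert_rule(rule_id = r$id %||% r$rule_id,
               concepts = unlist(r$concepts),
               value_op = r$value_op,
               value_threshold = r$value_threshold,
               min_count = r$min_count %||% 1L,
               window_days = r$window_days,
               scope = r$scope %||% "all",
               active_window = c(r$active_from %||% "1900-01-01",
                                 r$active_to %||% "2100-01-01"))
  })
}
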