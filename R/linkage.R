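#' Match patients across two source extracts
#'
#' Two-stage deterministic linkage. Stage 1 matches patients whose
#' pseudonym keys are literally identical in both extracts (the situation
#' when both routes key on the same identifier, e.g. an NHS-number-derived
#' pseudonym). Stage 2 matches the remainder on an exact demographic
#' fingerprint: (age, sex, three earliest distinct journal dates). A
#' fingerprint that occurs more than once on either side is ambiguous and
#' those patients are left unmatched rather than guessed. The result is
#' symmetric: swapping the sources mirrors the pairs and unique sets.
#'
#' @param a,b `source_extract` objects.
#' @return a `match_result`: list with `matched_pairs`
#'   (`data.table(key_a, key_b, method)` where method is `exact_key` or
#'   `demographic`), `unique_a`, `unique_b` (character vectors of
#'   unmatched keys).
#' @export
match_patients <- function(a, b) {
  validate_extract(a, "source a")
  validate_extract(b, "source b")

  keys_a <- a$patients$patient_key
  keys_b <- b$patients$patient_key

  shared <- intersect(keys_a, keys_b)
  pairs <- list()
  if (length(shared)) {
    pairs[[1L]] <- data.table(key_a = shared, key_b = shared,
                              method = "exact_key")
  }

  rest_a <- setdiff(keys_a, shared)
  rest_b <- setdiff(keys_b, shared)
  if (length(rest_a) && length(rest_b)) {
    fa <- patient_fingerprints(a, rest_a)
    fb <- patient_fingerprints(b, rest_b)
    ## drop ambiguous fingerprints (>= 2 equally good candidates)
    fa <- fa[!fingerprint %in% fa[duplicated(fingerprint), fingerprint]]
    fb <- fb[!fingerprint %in% fb[duplicated(fingerprint), fingerprint]]
    hit <- merge(fa, fb, by = "fingerprint", suffixes = c("_a", "_b"))
    if (nrow(hit)) {
      pairs[[length(pairs) + 1L]] <-
        data.table(key_a = hit$patient_key_a, key_b = hit$patient_key_b,
                   method = "demographic")
    }
  }
  matched <- if (length(pairs)) data.table::rbindlist(pairs) else {
    data.table(key_a = character(0), key_b = character(0), method = character(0))
  }
  data.table::setorder(matched, key_a)
  structure(list(matched_pairs = matched,
                 unique_a = sort(setdiff(keys_a, matched$key_a)),
                 unique_b = sort(setdiff(keys_b, matched$key_b))),
            class = "match_result")
}

patient_fingerprints <- function(x, keys) {
  dates <- x$journal[patient_key %in% keys,
                     .(fp_dates = paste(sort(unique(date))[1:3], collapse = "|")),
                     by = patient_key]
  fp <- merge(x$patients[patient_key %in% keys, .(patient_key, age, sex)],
              dates, by = "patient_key", all.x = TRUE)
  fp[is.na(fp_dates), fp_dates := ""]
  fp[, .(patient_key, fingerprint = paste(age, sex, fp_dates, sep = "/"))]
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d matched (%d exact-key, %d demographic), %d unique to a, %d unique to b\n",
              nrow(x$matched_pairs), sum(x$matched_pairs$method == "exact_key"),
              sum(x$matched_pairs$method == "demographic"),
              length(x$unique_a), length(x$unique_b)))
  invisible(x)
}

#' Merge prescription records of matched patients across two sources
#'
#' Pools the prescription records of every matched patient pair, removes
#' cross-source duplicates (records equal on patient, code, date and
#' quantity collapse to one), and counts the records unique to either
#' source — the record-level concordance measure of the dual-verification
#' design.
#'
#' @param a,b `source_extract` objects.
#' @param m a [match_patients()] result for `a`, `b`.
#' @return list with `records` (merged unique records keyed by `key_a`
#'   with presence flags `in_a`, `in_b`), and counts `total_merged`,
#'   `unique_a`, `unique_b`, `pct_matched` (unrounded percentage of merged
#'   records present in both sources).
#' @export
merge_prescriptions <- function(a, b, m) {
  stopifnot(inherits(m, "match_result"))
  merge_records(a, b, m, kind = "prescription",
                by_cols = c("code", "date", "quantity"))
}

## shared merge for prescription and diagnosis record comparison
merge_records <- function(a, b, m, kind, by_cols, codes = NULL) {
  pairs <- m$matched_pairs
  sel <- function(x, keycol) {
    jr <- x$journal[record_kind == kind]
    if (!is.null(codes)) jr <- jr[code %in% codes]
    jr <- jr[patient_key %in% pairs[[keycol]]]
    map <- stats::setNames(pairs$key_a, pairs[[keycol]])
    jr[, .(key_a = map[patient_key], code, date, quantity)]
  }
  ra <- unique(sel(a, "key_a")[, c("key_a", by_cols), with = FALSE])
  rb <- unique(sel(b, "key_b")[, c("key_a", by_cols), with = FALSE])
  ra[, in_a := TRUE]
  rb[, in_b := TRUE]
  mg <- merge(ra, rb, by = c("key_a", by_cols), all = TRUE)
  mg[is.na(in_a), in_a := FALSE]
  mg[is.na(in_b), in_b := FALSE]
  total <- nrow(mg)
  ua <- mg[in_a & !in_b, .N]
  ub <- mg[!in_a & in_b, .N]
  list(records = mg[], total_merged = total, unique_a = ua, unique_b = ub,
       pct_matched = if (total > 0) 100 * (total - ua - ub) / total else NA_real_)
}

#' Cross-classify matched patients by a condition in each source
#'
#' @param a,b `source_extract` objects.
#' @param m a [match_patients()] result.
#' @param concept diagnosis concept from the code list (e.g. `"copd_dx"`).
#' @param codelist the code list.
#' @return a [two_by_two()] agreement table over the matched patients.
#' @export
compare_condition <- function(a, b, m, concept, codelist = load_codelist()) {
  stopifnot(inherits(m, "match_result"))
  codes <- concept_codes(codelist, concept)
  pairs <- m$matched_pairs
  pos_a <- unique(a$journal[record_kind == "event" & code %in% codes, patient_key])
  pos_b <- unique(b$journal[record_kind == "event" & code %in% codes, patient_key])
  ia <- pairs$key_a %in% pos_a
  ib <- pairs$key_b %in% pos_b
  two_by_two(both_pos = sum(ia & ib), a_only = sum(ia & !ib),
             b_only = sum(!ia & ib), both_neg = sum(!ia & !ib))
}

#' Construct a 2x2 agreement table
#'
#' @param both_pos,a_only,b_only,both_neg non-negative cell counts:
#'   condition present in both sources, in source A only, in source B
#'   only, in neither.
#' @return a `two_by_two` object.
#' @export
two_by_two <- function(both_pos, a_only, b_only, both_neg) {
  cells <- c(both_pos = both_pos, a_only = a_only,
             b_only = b_only, both_neg = both_neg)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    stop("two_by_two cells must be non-negative integers", call. = FALSE)
  }
  cells <- as.list(stats::setNames(as.integer(cells), names(cells)))
  structure(cells, class = "two_by_two")
}

#' Cohen's kappa on a 2x2 agreement table
#'
#' Chance-corrected agreement: kappa = (p_o - p_e) / (1 - p_e), where p_o
#' is the observed agreement proportion and p_e the agreement expected
#' from the table margins. On a degenerate table where every patient
#' falls in one class in both sources (expected agreement 1), kappa is
#' reported as 1 with attribute `degenerate = TRUE`, so that the
#' identical-extract case does not error inside reports.
#'
#' @param t a [two_by_two()] table (total > 0).
#' @return kappa in `[-1, 1]` (numeric scalar, possibly with attribute
#'   `degenerate`).
#' @export
#' @examples
#' cohen_kappa(two_by_two(75, 1, 2, 3375))  # ~0.98
cohen_kappa <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  n <- t$both_pos + t$a_only + t$b_only + t$both_neg
  if (n <= 0) stop("kappa undefined on an empty table", call. = FALSE)
  po <- (t$both_pos + t$both_neg) / n
  pe <- ((t$both_pos + t$a_only) * (t$both_pos + t$b_only) +
           (t$both_neg + t$b_only) * (t$both_neg + t$a_only)) / n^2
  if (pe >= 1) {
    ## margins force agreement; only reachable when off-diagonals are zero
    return(structure(1, degenerate = TRUE))
  }
  (po - pe) / (1 - pe)
}

#' Full two-source concordance report
#'
#' Composes patient matching, prescription-record merging, diagnosis-record
#' merging and condition agreement into the verification summary the
#' dual-extraction design calls for. All percentages are stored unrounded;
#' formatting to printed precision is left to the caller.
#'
#' @param a,b `source_extract` objects.
#' @param codelist the code list.
#' @param concept diagnosis concept for the agreement table (default
#'   `"copd_dx"`).
#' @param registry_total number of patients the external registry says
#'   exist (denominator of the patient-match percentage); defaults to the
#'   union of patients seen by either source.
#' @return a `concordance_report` list: `n_matched`, `registry_total`,
#'   `pct_matched`, `unique_a`, `unique_b`, `prescription` (counts from
#'   [merge_prescriptions()]), `diagnosis` (`total`, `missing_a`,
#'   `missing_b`, `pct_missing_a`, `pct_missing_b`), `condition_table`,
#'   `kappa`, `kappa_degenerate`.
#' @export
verification_report <- function(a, b, codelist = load_codelist(),
                                concept = "copd_dx", registry_total = NULL) {
  m <- match_patients(a, b)
  n_matched <- nrow(m$matched_pairs)
  if (is.null(registry_total)) {
    registry_total <- n_matched + length(m$unique_a) + length(m$unique_b)
  }
  rx <- merge_prescriptions(a, b, m)
  dx_codes <- codelist[concept %in% diagnosis_concepts(codelist), code]
  dx <- merge_records(a, b, m, kind = "event", by_cols = c("code", "date"),
                      codes = dx_codes)
  tab <- compare_condition(a, b, m, concept, codelist)
  kap <- cohen_kappa(tab)
  structure(list(
    n_matched = n_matched,
    registry_total = registry_total,
    pct_matched = 100 * n_matched / registry_total,
    unique_a = length(m$unique_a),
    unique_b = length(m$unique_b),
    match = m,
    prescription = rx[c("total_merged", "unique_a", "unique_b", "pct_matched")],
    diagnosis = list(total = dx$total_merged,
                     missing_a = dx$unique_b,   # present only in B => absent from A
                     missing_b = dx$unique_a,
                     pct_missing_a = if (dx$total_merged > 0)
                       100 * dx$unique_b / dx$total_merged else NA_real_,
                     pct_missing_b = if (dx$total_merged > 0)
                       100 * dx$unique_a / dx$total_merged else NA_real_),
    condition_concept = concept,
    condition_table = tab,
    kappa = as.numeric(kap),
    kappa_degenerate = isTRUE(attr(kap, "degenerate"))
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report>\n")
  cat(sprintf("  patients: %d matched of %d registered (%.1f%%); %d unique to a, %d unique to b\n",
              x$n_matched, x$registry_total, x$pct_matched, x$unique_a, x$unique_b))
  cat(sprintf("  prescriptions: %d merged, %d unique to a, %d unique to b (%.2f%% matched)\n",
              x$prescription$total_merged, x$prescription$unique_a,
              x$prescription$unique_b, x$prescription$pct_matched))
  cat(sprintf("  diagnoses: %d merged, %d missing from a, %d missing from b (%.1f%% missing from b)\n",
              x$diagnosis$total, x$diagnosis$missing_a, x$diagnosis$missing_b,
              x$diagnosis$pct_missing_b))
  t <- x$condition_table
  cat(sprintf("  %s agreement: (%d, %d, %d, %d), kappa = %.2f%s\n",
              x$condition_concept, t$both_pos, t$a_only, t$b_only, t$both_neg,
              x$kappa, if (x$kappa_degenerate) " (degenerate)" else ""))
  invisible(x)
}
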