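## Internal helpers: seeds, dates, validation.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code never perturbs the
#' caller's RNG stream. All stochastic operations in the package route
#' through this.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a per-stage seed from a global seed; stays below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1009L * as.integer(offset)) %% 2147483647L
}

as_idate <- function(x) {
  if (inherits(x, "IDate")) return(x)
  if (inherits(x, "Date")) return(data.table::as.IDate(x))
  if (is.numeric(x)) return(data.table::as.IDate(as.integer(x), origin = "1970-01-01"))
  out <- suppressWarnings(data.table::as.IDate(as.character(x), format = "%Y-%m-%d"))
  if (anyNA(out) && !all(is.na(x) | !nzchar(as.character(x)))) {
    bad <- which(is.na(out) & nzchar(as.character(x)))[1L]
    stop(sprintf("unparseable ISO-8601 date '%s'", as.character(x)[bad]), call. = FALSE)
  }
  out
}

## Half-open [start, end) window from a length-2 date-ish vector.
as_window <- function(w, what = "window") {
  if (length(w) != 2L) stop(sprintf("%s must have two dates", what), call. = FALSE)
  w <- as_idate(w)
  if (anyNA(w) || w[1L] >= w[2L]) {
    stop(sprintf("%s must satisfy start < end", what), call. = FALSE)
  }
  w
}

in_window <- function(dates, window) {
  !is.na(dates) & dates >= window[1L] & dates < window[2L]
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be a proportion in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

check_rate <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop(sprintf("'%s' must be a non-negative rate", name), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Union length (in days) of half-open day intervals [start, start+len).
## Used to cap overlapping prescription supplies at calendar coverage.
interval_union_days <- function(start, len, clip = NULL) {
  stopifnot(length(start) == length(len))
  if (length(start) == 0L) return(0L)
  s <- as.integer(start)
  e <- s + as.integer(len)
  if (!is.null(clip)) {
    s <- pmax(s, as.integer(clip[1L]))
    e <- pmin(e, as.integer(clip[2L]))
  }
  keep <- e > s
  s <- s[keep]; e <- e[keep]
  if (length(s) == 0L) return(0L)
  o <- order(s)
  s <- s[o]; e <- e[o]
  total <- 0L
  cur_s <- s[1L]; cur_e <- e[1L]
  if (length(s) > 1L) {
    for (i in 2L:length(s)) {
      if (s[i] > cur_e) {
        total <- total + (cur_e - cur_s)
        cur_s <- s[i]; cur_e <- e[i]
      } else {
        cur_e <- max(cur_e, e[i])
      }
    }
  }
  total + (cur_e - cur_s)
}
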