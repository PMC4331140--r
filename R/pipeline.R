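#' Read and validate a run configuration
#'
#' A YAML file drives the full pipeline: generator parameters, a
#' corruption profile per source, cohort switches, the follow-up window,
#' and the alert rules path. Paths are resolved relative to the config
#' file. All randomness derives from the single `seed` via fixed
#' per-stage offsets, so a config + seed pair reproduces every artifact
#' byte for byte.
#'
#' @param path YAML config path.
#' @return a validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
  y <- yaml::read_yaml(path)
  base_dir <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) return(normalizePath(p))
    file.path(base_dir, p)
  }
  cfg <- list(
    seed = check_count(y$seed %||% 1L, "seed"),
    out_dir = y$out_dir %||% "results",
    codelist_path = resolve(y$codelist),
    generator = y$generator %||% list(),
    sources = y$sources %||% list(
      sir = list(drop_patient_prob = 0.005,
                 drop_record_prob = list(prescription = 0.0001, event = 0.005)),
      apollo = list(drop_patient_prob = 0.002,
                    drop_record_prob = list(prescription = 0.0002, event = 0.0001))),
    followup_window = y$followup_window %||% c("2009-01-01", "2010-01-01"),
    alert_rules = resolve(y$alert_rules),
    alert_days = check_count(y$alert_days %||% 28L, "alert_days", min = 1L)
  )
  if (!is.null(cfg$codelist_path) && !file.exists(cfg$codelist_path)) {
    stop(sprintf("code list not found: %s", cfg$codelist_path), call. = FALSE)
  }
  if (!is.null(cfg$alert_rules) && !file.exists(cfg$alert_rules)) {
    stop(sprintf("alert rules not found: %s", cfg$alert_rules), call. = FALSE)
  }
  if (length(cfg$sources) != 2L) stop("config must define exactly two sources", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Run the full pipeline: generate, verify, phenotype, rate, alert
#'
#' Executes the stages in sequence, writing each artifact under
#' `out_dir`: the two corrupted source extracts, the concordance report
#' (`verification.json`), the asthma and COPD cohorts with flow counts,
#' the stratified rate tables, the hospital-days summary, an alert log
#' (`alerts.jsonl`), and a `manifest.json` with the seeds, package
#' version and an MD5 checksum per file. A failing stage halts with the
#' stage name in the error.
#'
#' @param config a [read_run_config()] result (or path to one).
#' @param out_dir optional override of the configured output directory.
#' @return invisibly, a list with the in-memory artifacts.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  codelist <- load_codelist(config$codelist_path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ## 1. ground truth
  truth <- stage("generate", {
    gp <- do.call(generator_params,
                  c(config$generator, list(seed = derive_seed(config$seed, 1L))))
    generate_population(gp, codelist)
  })

  ## 2. two corrupted extracts
  extracts <- stage("corrupt", {
    src <- names(config$sources)
    out <- list()
    for (i in seq_along(src)) {
      sc <- config$sources[[i]]
      prof <- corruption_profile(
        drop_patient_prob = sc$drop_patient_prob %||% 0,
        drop_record_prob = c(prescription = sc$drop_record_prob$prescription %||% 0,
                             event = sc$drop_record_prob$event %||% 0),
        duplicate_record_prob = sc$duplicate_record_prob %||% 0,
        seed = derive_seed(config$seed, 1L + i))
      ex <- corrupt_to_source(truth, prof, src[i])
      write_extract(ex, file.path(out_dir, "extracts", src[i]))
      out[[src[i]]] <- ex
    }
    out
  })

  ## 3. dual verification
  report <- stage("verify", {
    rep <- verification_report(extracts[[1L]], extracts[[2L]], codelist,
                               registry_total = nrow(truth$patients))
    jsonlite::write_json(
      rep[setdiff(names(rep), c("match", "condition_table"))],
      file.path(out_dir, "verification.json"),
      auto_unbox = TRUE, digits = NA)
    rep
  })

  ## 4. cohorts on source A
  a <- extracts[[1L]]
  cohorts <- stage("cohort", {
    out <- list()
    for (dz in c("asthma", "copd")) {
      ch <- build_cohort(a, cohort_spec(dz), codelist)
      data.table::fwrite(ch$members, file.path(out_dir, sprintf("cohort_%s.csv", dz)),
                         na = "")
      out[[dz]] <- ch
    }
    jsonlite::write_json(lapply(out, function(ch) as.list(ch$flow)),
                         file.path(out_dir, "flow.json"),
                         auto_unbox = TRUE, digits = NA)
    out
  })

  ## 5. outcomes
  rates <- stage("outcomes", {
    out <- list()
    summaries <- list()
    for (dz in c("asthma", "copd")) {
      ch <- cohorts[[dz]]
      strata <- stratify_by_baseline_exacerbations(ch)
      fu <- person_time(a$journal, ch$members$patient_key,
                        window = config$followup_window, codelist = codelist)
      rt <- hru_rates(ch, a$journal, strata = strata,
                      window = config$followup_window, codelist = codelist,
                      followup = fu)
      data.table::fwrite(rt, file.path(out_dir, sprintf("rates_%s.csv", dz)))
      summaries[[dz]] <- hospital_days_summary(ch, a$journal,
                                               window = config$followup_window,
                                               codelist = codelist, followup = fu)
      out[[dz]] <- rt
    }
    jsonlite::write_json(summaries, file.path(out_dir, "hospital_days.json"),
                         auto_unbox = TRUE, digits = NA)
    out
  })

  ## 6. alerts over the first weeks of follow-up, daily batches
  alerts <- stage("alerts", {
    rules <- if (is.null(config$alert_rules)) {
      list(alert_rule("resp_admission_any", "resp_admission"))
    } else read_alert_rules(config$alert_rules)
    eng <- alert_engine(rules, codelist)
    d0 <- as_idate(config$followup_window[[1L]])
    con <- file(file.path(out_dir, "alerts.jsonl"), "w")
    on.exit(close(con))
    for (k in seq_len(config$alert_days)) {
      day <- d0 + (k - 1L)
      batch <- a$journal[date == day]
      new <- ingest_batch(eng, batch, day)
      if (nrow(new)) {
        for (i in seq_len(nrow(new))) {
          writeLines(jsonlite::toJSON(as.list(new[i]), auto_unbox = TRUE,
                                      digits = NA), con)
        }
      }
    }
    eng$alerts
  })

  ## manifest: inputs, seeds, versions, checksums
  stage("manifest", {
    files <- setdiff(list.files(out_dir, recursive = TRUE, full.names = TRUE),
                     file.path(out_dir, "manifest.json"))
    manifest <- list(
      seed = config$seed,
      stage_seeds = list(generate = derive_seed(config$seed, 1L),
                         sources = vapply(seq_along(config$sources),
                                          function(i) derive_seed(config$seed, 1L + i),
                                          integer(1))),
      package_version = as.character(utils::packageVersion("emrcohort")),
      files = lapply(stats::setNames(files, sub(paste0("^", out_dir, "/?"), "", files)),
                     function(f) unname(tools::md5sum(f)))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  invisible(list(truth = truth, extracts = extracts, report = report,
                 cohorts = cohorts, rates = rates, alerts = alerts,
                 out_dir = out_dir))
}
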