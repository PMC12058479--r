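#' End-to-end pipeline configuration
#'
#' Bundles everything one pipeline run needs: an input source (either a
#' [sim_config()] simulation block or the five quarterly file paths), the
#' event definition, screening thresholds and modelling settings.
#'
#' @param simulate A [sim_config()], or `NULL` when reading files.
#' @param quarter_files Named character vector/list with elements `demo`,
#'   `drug`, `reac`, `outc`, `ther`, or `NULL` when simulating.
#' @param event_terms Event PT list (default the single PT `"CATARACT"`).
#' @param exclude_drugs Ingredients excluded from screening (medications
#'   intended to treat the event).
#' @param name_map Optional brand-to-ingredient tibble.
#' @param criteria [signal_criteria()] for the signal screen.
#' @param k_folds,grid_size LASSO cross-validation settings.
#' @param seed Integer seed for fold assignment (and, for simulation runs,
#'   passed through to the generator unless the sim block sets its own).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, quarter_files = NULL,
                            event_terms = "CATARACT", exclude_drugs = NULL,
                            name_map = NULL, criteria = signal_criteria(),
                            k_folds = 10, grid_size = 100, seed = 1L) {
  if (is.null(simulate) && is.null(quarter_files)) {
    abort("pipeline_config needs either a simulation block or quarter_files")
  }
  if (!is.null(quarter_files)) {
    need <- c("demo", "drug", "reac", "outc", "ther")
    if (!all(need %in% names(quarter_files))) {
      abort("quarter_files must name demo, drug, reac, outc and ther paths")
    }
  }
  structure(
    list(simulate = simulate, quarter_files = quarter_files,
         event_terms = event_terms, exclude_drugs = exclude_drugs,
         name_map = name_map, criteria = criteria, k_folds = k_folds,
         grid_size = grid_size, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full screening-and-modelling pipeline
#'
#' Executes ingest, cleaning cascade, disproportionality screen,
#' LASSO-then-multivariate risk model, time-to-onset analysis and the
#' descriptive reports, writing every stage output to `out_dir` together
#' with a run manifest (configuration echo, seed, provenance counters,
#' package version, timestamp). Re-running the same configuration and seed
#' reproduces every stage output byte for byte; only the manifest
#' timestamp differs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results (`clean`,
#'   `signals`, `candidates`, `lasso`, `fit`, `roc`, `onset_records`,
#'   `onset_summary`, `baseline`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)

  # ingest
  if (!is.null(config$simulate)) {
    sim <- simulate_reports(config$simulate)
    rs <- sim$reports
  } else {
    qf <- config$quarter_files
    missing <- unlist(qf)[!file.exists(unlist(qf))]
    if (length(missing) > 0) {
      abort(paste0("missing input path(s): ", paste(missing, collapse = ", ")),
            class = "faersignal_missing_input")
    }
    rs <- read_faers_quarter(qf$demo, qf$drug, qf$reac, qf$outc, qf$ther)
  }
  clean <- clean_reports(rs, name_map = config$name_map)
  write_report_tsv(clean, path("clean.tsv"))
  jsonlite::write_json(provenance(clean), path("provenance.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)

  # disproportionality screen
  tables <- contingency_tables(clean, config$event_terms,
                               exclude_drugs = config$exclude_drugs)
  stats <- ror_stats(tables, min_cases_m = config$criteria$min_cases)
  signals <- screen_signals(stats, config$criteria)
  readr::write_tsv(signals, path("signals.tsv"))
  readr::write_tsv(volcano_table(stats), path("volcano.tsv"))

  # risk model
  cands <- candidate_drugs(stats, min_cases_cand = config$criteria$min_cases,
                           alpha_cand = config$criteria$alpha_adj)
  lasso <- NULL; fit <- NULL; roc <- NULL
  if (length(cands) > 0) {
    dm <- build_design_matrix(clean, cands, config$event_terms)
    lasso <- fit_lasso_logistic(dm, grid_size = config$grid_size,
                                k_folds = config$k_folds,
                                seed = config$seed)
    dm_sel <- if (length(lasso$selected_drugs) > 0) {
      select_columns(dm, lasso$selected_drugs)
    } else {
      dm
    }
    fit <- fit_logistic(dm_sel)
    roc <- model_roc(fit)
    readr::write_tsv(tidy(lasso), path("lasso_path.tsv"))
    readr::write_tsv(tidy(fit), path("model.tsv"))
    readr::write_tsv(roc$points, path("roc.tsv"))
  }

  # time to onset, pooled over the event series
  events <- filter_event_reports(clean, config$event_terms)
  onset_records <- extract_onset(events)
  onset_summary <- if (nrow(onset_records) > 0) {
    summarize_onset(onset_records)
  } else {
    NULL
  }
  if (!is.null(onset_summary)) {
    jsonlite::write_json(
      dplyr::select(onset_summary, -"quantiles"), path("onset_summary.json"),
      auto_unbox = FALSE, digits = NA, pretty = TRUE)
    readr::write_tsv(onset_curve(onset_records), path("onset_curve.tsv"))
  }

  # descriptive reports on the event series
  baseline <- baseline_table(events)
  jsonlite::write_json(
    list(n_total = baseline$n_total, age = baseline$age,
         weight = baseline$weight, sex = baseline$sex,
         outcome = baseline$outcome, country = baseline$country),
    path("baseline.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_tsv(yearly_counts(events), path("yearly.tsv"))
  readr::write_tsv(age_pyramid(events), path("pyramid.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("faersignal")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    event_terms = config$event_terms,
    criteria = config$criteria,
    k_folds = config$k_folds,
    grid_size = config$grid_size,
    input = if (is.null(config$simulate)) "quarter_files" else "simulation",
    simulate_seed = if (is.null(config$simulate)) NULL else config$simulate$seed,
    n_candidates = length(cands),
    n_selected = if (is.null(lasso)) 0L else length(lasso$selected_drugs),
    provenance = provenance(clean),
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(manifest, path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(clean = clean, signals = signals, candidates = cands,
                 lasso = lasso, fit = fit, roc = roc,
                 onset_records = onset_records,
                 onset_summary = onset_summary, baseline = baseline,
                 manifest = manifest))
}
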