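#' Configuration for the synthetic spontaneous-report generator
#'
#' Builds a validated configuration for [simulate_reports()]. The defaults
#' describe the drug-induced cataract study conditions the package is
#' exercised under: a panel of 30 named drugs at 1% exposure each, five of
#' which carry injected reporting odds ratios of 3, 4, 6, 10 and 14 (the
#' rest are null), a background pool absorbing the remaining exposure mass,
#' demographics matching the cataract case series (age 66.92 +/- 11.95 y,
#' 71.16% female, weight 72.44 +/- 22.53 kg), a log-normal
#' therapy-start-to-onset lag with median 449 days, and contamination in
#' the form of duplicate case versions, missing demographics and
#' implausible ages/weights.
#'
#' @param n_reports Number of truth reports to generate (duplicates come on
#'   top).
#' @param drugs Tibble with columns `ingredient`, `exposure_probability`,
#'   `true_log_or`. Exposure probabilities must lie in (0,1) and sum to at
#'   most 1; any remaining mass is spread over `n_background` null filler
#'   drugs so that the case/non-case comparator is not exhausted by the
#'   named panel.
#' @param baseline_event_logit Intercept of the event model on the logit
#'   scale; the default corresponds to a 5% baseline event rate.
#' @param demog Named list of demographic parameters: `age_mean`, `age_sd`
#'   (years), `prob_female`, `weight_mean`, `weight_sd` (kg),
#'   `sex_effect_log_or` (female vs male), `age_effect_per_year`,
#'   `weight_effect_per_kg` (log-odds per unit). Covariate effects are
#'   centred at the configured means, so `baseline_event_logit` remains the
#'   population-average logit.
#' @param onset Named list: `log_median_days` and `log_sd` of the
#'   log-normal therapy-start-to-event lag.
#' @param duplicate_rate Fraction of cases re-emitted as an extra,
#'   earlier-dated version (in `[0,1)`).
#' @param missing_demog_rate Fraction of reports with one demographic field
#'   blanked (in `[0,1)`).
#' @param implausible_rate Fraction of reports given an implausible age
#'   (>120 y) or weight (>400 kg) (in `[0,1)`).
#' @param year_range Integer vector `c(first, last)` of report years.
#' @param event_pt Preferred term assigned to event reports.
#' @param n_background Number of null filler drugs sharing the exposure
#'   mass not claimed by `drugs`.
#' @param seed Integer seed; identical configurations generate identical
#'   output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_reports = 2e5,
                       drugs = default_drug_panel(),
                       baseline_event_logit = qlogis(0.05),
                       demog = list(),
                       onset = list(),
                       duplicate_rate = 0.05,
                       missing_demog_rate = 0.05,
                       implausible_rate = 0.005,
                       year_range = c(2004L, 2024L),
                       event_pt = "CATARACT",
                       n_background = 20,
                       seed = 1L) {
  demog <- modifyList(default_demog(), demog)
  onset <- modifyList(default_onset(), onset)
  cfg <- structure(
    list(n_reports = n_reports, drugs = tibble::as_tibble(drugs),
         baseline_event_logit = baseline_event_logit, demog = demog,
         onset = onset, duplicate_rate = duplicate_rate,
         missing_demog_rate = missing_demog_rate,
         implausible_rate = implausible_rate,
         year_range = as.integer(year_range), event_pt = event_pt,
         n_background = as.integer(n_background), seed = as.integer(seed)),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

default_demog <- function() {
  list(age_mean = 66.92, age_sd = 11.95, prob_female = 0.7116,
       weight_mean = 72.44, weight_sd = 22.53,
       sex_effect_log_or = 0.1, age_effect_per_year = 0.02,
       weight_effect_per_kg = 0.002)
}

default_onset <- function() {
  # median 449 d; sigma fitted from the IQR ratio 901/150
  list(log_median_days = log(449),
       log_sd = log(901 / 150) / (2 * qnorm(0.75)))
}

#' @rdname sim_config
#' @export
default_drug_panel <- function() {
  tibble(
    ingredient = sprintf("DRUG%02d", 1:30),
    exposure_probability = 0.01,
    true_log_or = c(log(c(3, 4, 6, 10, 14)), rep(0, 25))
  )
}

validate_sim_config <- function(cfg) {
  fail <- function(field, why) {
    abort(paste0("invalid sim_config field `", field, "`: ", why))
  }
  if (!is.numeric(cfg$n_reports) || length(cfg$n_reports) != 1 ||
      is.na(cfg$n_reports) || cfg$n_reports < 0) {
    fail("n_reports", "must be a single non-negative number")
  }
  d <- cfg$drugs
  if (nrow(d) == 0) fail("drugs", "drug panel must be non-empty")
  if (!all(c("ingredient", "exposure_probability", "true_log_or") %in% names(d))) {
    fail("drugs", "needs columns ingredient, exposure_probability, true_log_or")
  }
  if (any(d$exposure_probability <= 0 | d$exposure_probability >= 1)) {
    fail("drugs", "exposure probabilities must lie in (0, 1)")
  }
  if (sum(d$exposure_probability) > 1 + 1e-12) {
    fail("drugs", "exposure probabilities must sum to at most 1")
  }
  for (r in c("duplicate_rate", "missing_demog_rate", "implausible_rate")) {
    v <- cfg[[r]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v >= 1) {
      fail(r, "must lie in [0, 1)")
    }
  }
  if (length(cfg$year_range) != 2 || anyNA(cfg$year_range) ||
      cfg$year_range[1] > cfg$year_range[2]) {
    fail("year_range", "must be c(first, last) with first <= last")
  }
  if (cfg$demog$age_sd <= 0 || cfg$demog$weight_sd <= 0) {
    fail("demog", "age_sd and weight_sd must be positive")
  }
  if (cfg$demog$prob_female < 0 || cfg$demog$prob_female > 1) {
    fail("demog", "prob_female must lie in [0, 1]")
  }
  if (cfg$onset$log_sd <= 0) fail("onset", "log_sd must be positive")
  if (sum(d$exposure_probability) < 1 - 1e-12 && cfg$n_background < 1) {
    fail("n_background", "needed when named exposure probabilities sum below 1")
  }
  cfg
}

noise_pt_pool <- function() {
  c("NAUSEA", "HEADACHE", "DIZZINESS", "RASH", "FATIGUE",
    "VOMITING", "PYREXIA", "DIARRHOEA", "ARTHRALGIA", "INSOMNIA")
}

# Table-1-like single-outcome distribution used by the generator.
outcome_probs <- function() {
  c("other-serious" = 0.6205, "missing" = 0.1982,
    "hospitalization" = 0.1476, "disability" = 0.0147, "death" = 0.0128,
    "life-threatening" = 0.0055, "congenital-anomaly" = 0.0004,
    "required-intervention" = 0.0003)
}

#' Generate a synthetic spontaneous-report set with known ground truth
#'
#' Draws `n_reports` individual case safety reports from the configured
#' generative model. Each report receives demographics from the configured
#' distributions and exactly one primary-suspect drug sampled by exposure
#' probability; its event indicator is Bernoulli with
#' `logit^-1(alpha + true_log_or[drug] + centred demographic effects)`.
#' Event reports get an event date at `therapy_start` plus a log-normal
#' lag. Contamination is applied last: a fraction of cases is re-emitted as
#' an extra *earlier-dated* version (so the keep-latest deduplication rule
#' provably recovers the truth copy), and some reports have demographics
#' blanked or replaced by implausible values. The companion truth ledger
#' records everything needed for parameter-recovery tests.
#'
#' @param config A [sim_config()].
#' @return A list with elements `reports` (a [report_set]) and `truth` (a
#'   `truth_ledger`: tibbles `drugs`, `reports`, `duplicates`, `injected`).
#' @examples
#' sim <- simulate_reports(sim_config(n_reports = 500, seed = 42))
#' sim$reports
#' head(sim$truth$drugs)
#' @export
simulate_reports <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  n <- as.integer(config$n_reports)

  panel <- config$drugs
  spare <- 1 - sum(panel$exposure_probability)
  if (spare > 1e-12) {
    panel <- dplyr::bind_rows(
      panel,
      tibble(ingredient = sprintf("BACKGROUND%02d", seq_len(config$n_background)),
             exposure_probability = spare / config$n_background,
             true_log_or = 0)
    )
  }

  if (n == 0) {
    rs <- empty_report_set()
    rs <- add_provenance(rs, "simulated", "0 reports")
    truth <- structure(
      list(drugs = dplyr::mutate(panel, n_exposed = 0L),
           reports = tibble(report_id = character(), case_id = character(),
                            drug = character(), linear_predictor = double(),
                            event = integer()),
           duplicates = tibble(case_id = character(),
                               truth_report_id = character(),
                               duplicate_report_id = character()),
           injected = tibble(report_id = character(), field = character(),
                             kind = character())),
      class = "truth_ledger")
    return(list(reports = rs, truth = truth))
  }

  dg <- config$demog
  drug_idx <- sample.int(nrow(panel), n, replace = TRUE,
                         prob = panel$exposure_probability)
  age    <- round(pmin(pmax(rnorm(n, dg$age_mean, dg$age_sd), 0), 115))
  female <- rbinom(n, 1, dg$prob_female)
  weight <- round(pmin(pmax(rnorm(n, dg$weight_mean, dg$weight_sd), 1), 350), 1)

  lp <- config$baseline_event_logit +
    panel$true_log_or[drug_idx] +
    dg$age_effect_per_year * (age - dg$age_mean) +
    dg$weight_effect_per_kg * (weight - dg$weight_mean) +
    dg$sex_effect_log_or * (female - dg$prob_female)
  event <- rbinom(n, 1, plogis(lp))

  years <- seq(config$year_range[1], config$year_range[2])
  year_start <- as.Date(sprintf("%d-01-01", years))
  yr <- sample(years, n, replace = TRUE)
  therapy_start <- year_start[match(yr, years)] +
    sample.int(365, n, replace = TRUE) - 1L
  lag_days <- pmax(1, round(rlnorm(n, config$onset$log_median_days,
                                   config$onset$log_sd)))
  event_date <- as.Date(ifelse(event == 1, therapy_start + lag_days, NA),
                        origin = "1970-01-01")
  report_ref <- as.Date(ifelse(event == 1, event_date, therapy_start),
                        origin = "1970-01-01")
  version_date <- report_ref + sample(30:365, n, replace = TRUE)
  therapy_end <- therapy_start + sample(30:730, n, replace = TRUE)

  case_id   <- sprintf("C%08d", seq_len(n))
  report_id <- paste0(case_id, "-2")

  reports <- tibble(
    report_id = report_id, case_id = case_id,
    version_date = version_date, event_date = event_date,
    report_year = 1900L + as.POSIXlt(version_date)$year,
    age_years = age, sex = ifelse(female == 1, "female", "male"),
    weight_kg = weight, country = "US"
  )
  drugs <- tibble(
    report_id = report_id,
    name_raw = panel$ingredient[drug_idx],
    ingredient = panel$ingredient[drug_idx],
    role = "primary-suspect",
    therapy_start = therapy_start, therapy_end = therapy_end
  )
  pts <- ifelse(event == 1, config$event_pt,
                sample(noise_pt_pool(), n, replace = TRUE))
  reactions <- tibble(report_id = report_id, pt = pts)
  op <- outcome_probs()
  outcomes <- tibble(
    report_id = report_id,
    outcome = sample(names(op), n, replace = TRUE, prob = op)
  )

  # duplicate case versions: earlier-dated copies of a sample of cases
  n_dup <- round(config$duplicate_rate * n)
  duplicates <- tibble(case_id = character(), truth_report_id = character(),
                       duplicate_report_id = character())
  if (n_dup > 0) {
    pick <- sort(sample.int(n, n_dup))
    dup_reports <- reports[pick, ]
    dup_reports$report_id <- paste0(dup_reports$case_id, "-1")
    dup_reports$version_date <- dup_reports$version_date -
      sample(30:365, n_dup, replace = TRUE)
    dup_reports$report_year <-
      1900L + as.POSIXlt(dup_reports$version_date)$year
    remap <- function(tbl) {
      kid <- tbl[tbl$report_id %in% reports$report_id[pick], ]
      kid$report_id <- paste0(sub("-2$", "", kid$report_id), "-1")
      kid
    }
    duplicates <- tibble(case_id = dup_reports$case_id,
                         truth_report_id = reports$report_id[pick],
                         duplicate_report_id = dup_reports$report_id)
    reports   <- dplyr::bind_rows(reports, dup_reports)
    drugs     <- dplyr::bind_rows(drugs, remap(drugs))
    reactions <- dplyr::bind_rows(reactions, remap(reactions))
    outcomes  <- dplyr::bind_rows(outcomes, remap(outcomes))
  }

  # missingness and implausible-value injection, applied last
  n_tot <- nrow(reports)
  injected <- tibble(report_id = character(), field = character(),
                     kind = character())
  n_miss <- round(config$missing_demog_rate * n_tot)
  if (n_miss > 0) {
    rows <- sample.int(n_tot, n_miss)
    fields <- sample(c("age_years", "sex", "weight_kg"), n_miss,
                     replace = TRUE)
    for (f in c("age_years", "weight_kg")) {
      reports[[f]][rows[fields == f]] <- NA_real_
    }
    reports$sex[rows[fields == "sex"]] <- "unknown"
    injected <- dplyr::bind_rows(
      injected, tibble(report_id = reports$report_id[rows],
                       field = fields, kind = "missing"))
  }
  n_impl <- round(config$implausible_rate * n_tot)
  if (n_impl > 0) {
    rows <- sample.int(n_tot, n_impl)
    fields <- sample(c("age_years", "weight_kg"), n_impl, replace = TRUE)
    ia <- rows[fields == "age_years"]
    iw <- rows[fields == "weight_kg"]
    reports$age_years[ia] <- round(runif(length(ia), 121, 160))
    reports$weight_kg[iw] <- round(runif(length(iw), 401, 600), 1)
    injected <- dplyr::bind_rows(
      injected, tibble(report_id = reports$report_id[rows],
                       field = fields, kind = "implausible"))
  }

  rs <- report_set(reports, drugs, reactions, outcomes)
  rs <- add_provenance(rs, "simulated",
                       paste0(n, " truth reports + ", n_dup, " duplicates"))

  truth <- structure(
    list(
      drugs = panel |>
        dplyr::mutate(n_exposed = as.integer(tabulate(drug_idx, nrow(panel)))),
      reports = tibble(report_id = report_id, case_id = case_id,
                       drug = panel$ingredient[drug_idx],
                       linear_predictor = lp, event = event),
      duplicates = duplicates,
      injected = injected
    ),
    class = "truth_ledger"
  )
  list(reports = rs, truth = truth)
}

empty_report_set <- function() {
  report_set(
    reports = tibble(report_id = character(), case_id = character(),
                     version_date = as.Date(character()),
                     event_date = as.Date(character()),
                     report_year = integer(), age_years = double(),
                     sex = character(), weight_kg = double(),
                     country = character()),
    drugs = tibble(report_id = character(), name_raw = character(),
                   ingredient = character(), role = character(),
                   therapy_start = as.Date(character()),
                   therapy_end = as.Date(character())),
    reactions = tibble(report_id = character(), pt = character()),
    outcomes = tibble(report_id = character(), outcome = character())
  )
}

#' Write a report set in the quarterly FAERS dialect
#'
#' Emits the five `$`-delimited files that [read_faers_quarter()] parses
#' (`demo.txt`, `drug.txt`, `reac.txt`, `outc.txt`, `ther.txt`). The writer
#' is the exact inverse of the parser on its column subset:
#' `read_faers_quarter()` on the written files reproduces the report set
#' field for field (after [normalize_drug_names()] with an empty map, since
#' the parser leaves `ingredient` unfilled). Duplicate case versions are
#' written as distinct rows — the writer never deduplicates.
#'
#' @param rs A [report_set].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_faers_quarter <- function(rs, out_dir) {
  stopifnot(is_report_set(rs))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste0("cannot create directory: ", out_dir))
  paths <- file.path(out_dir, c(demo = "demo.txt", drug = "drug.txt",
                                reac = "reac.txt", outc = "outc.txt",
                                ther = "ther.txt"))
  names(paths) <- c("demo", "drug", "reac", "outc", "ther")

  demo <- rs$reports |>
    dplyr::transmute(
      primaryid = .data$report_id, caseid = .data$case_id,
      fda_dt = pack_date(.data$version_date),
      event_dt = pack_date(.data$event_date),
      age = num_or_blank(.data$age_years),
      sex = dplyr::case_when(.data$sex == "female" ~ "F",
                             .data$sex == "male" ~ "M",
                             .default = ""),
      wt = num_or_blank(.data$weight_kg),
      occr_country = .data$country
    )

  drug_tbl <- rs$drugs |>
    dplyr::mutate(drug_seq = as.character(dplyr::row_number()),
                  .by = "report_id")
  drug <- drug_tbl |>
    dplyr::transmute(
      primaryid = .data$report_id, drug_seq = .data$drug_seq,
      role_cod = dplyr::case_when(
        .data$role == "primary-suspect" ~ "PS",
        .data$role == "secondary-suspect" ~ "SS",
        .data$role == "concomitant" ~ "C",
        .data$role == "interacting" ~ "I"),
      drugname = .data$name_raw
    )
  ther <- drug_tbl |>
    dplyr::filter(!is.na(.data$therapy_start) | !is.na(.data$therapy_end)) |>
    dplyr::transmute(primaryid = .data$report_id,
                     dsg_drug_seq = .data$drug_seq,
                     start_dt = pack_date(.data$therapy_start),
                     end_dt = pack_date(.data$therapy_end))

  reac <- rs$reactions |>
    dplyr::transmute(primaryid = .data$report_id, pt = .data$pt)

  outc <- rs$outcomes |>
    dplyr::filter(.data$outcome != "missing") |>
    dplyr::transmute(
      primaryid = .data$report_id,
      outc_cod = dplyr::case_when(
        .data$outcome == "death" ~ "DE",
        .data$outcome == "life-threatening" ~ "LT",
        .data$outcome == "hospitalization" ~ "HO",
        .data$outcome == "disability" ~ "DS",
        .data$outcome == "congenital-anomaly" ~ "CA",
        .data$outcome == "required-intervention" ~ "RI",
        .data$outcome == "other-serious" ~ "OT")
    )

  readr::write_delim(demo, paths[["demo"]], delim = "$", na = "")
  readr::write_delim(drug, paths[["drug"]], delim = "$", na = "")
  readr::write_delim(reac, paths[["reac"]], delim = "$", na = "")
  readr::write_delim(outc, paths[["outc"]], delim = "$", na = "")
  readr::write_delim(ther, paths[["ther"]], delim = "$", na = "")
  invisible(paths)
}

num_or_blank <- function(x) {
  out <- as.character(x)
  out[is.na(x)] <- ""
  out
}
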