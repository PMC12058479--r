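#' Time-to-onset records
#'
#' Extracts, for each event report, the lag in days from the start of
#' primary-suspect therapy to adverse-event onset. The therapy reference is
#' the *earliest* `therapy_start` among the report's primary-suspect
#' entries; the event reference is `event_date` (no imputation from the
#' report receipt date). Records with either date absent or a non-positive
#' lag are excluded and counted by reason.
#'
#' @param rs A cleaned, event-filtered [report_set] (see
#'   [filter_event_reports()]).
#' @param drugs Optional character vector restricting to given ingredients.
#' @return A tibble of onset records (`report_id`, `drug`, `days`) with an
#'   `exclusions` attribute: tibble of `reason` (`"missing date"`,
#'   `"non-positive lag"`) and `n`.
#' @export
extract_onset <- function(rs, drugs = NULL) {
  stopifnot(is_report_set(rs))
  ps <- rs$drugs |>
    dplyr::filter(.data$role == "primary-suspect")
  if (!is.null(drugs)) {
    ps <- dplyr::filter(ps, .data$ingredient %in% drugs)
  }
  cand <- ps |>
    dplyr::summarise(
      # drug first: it must see the original per-entry start dates, not the
      # summarized minimum
      drug = .data$ingredient[order(.data$therapy_start)][1],
      therapy_start = if (all(is.na(.data$therapy_start))) {
        as.Date(NA)
      } else {
        min(.data$therapy_start, na.rm = TRUE)
      },
      .by = "report_id"
    ) |>
    dplyr::inner_join(
      dplyr::select(rs$reports, "report_id", "event_date"),
      by = "report_id"
    ) |>
    dplyr::mutate(days = as.integer(.data$event_date - .data$therapy_start))

  missing_date <- is.na(cand$days)
  nonpos <- !missing_date & cand$days <= 0
  out <- cand |>
    dplyr::filter(!missing_date & !nonpos) |>
    dplyr::select("report_id", "drug", "days")
  attr(out, "exclusions") <- tibble(
    reason = c("missing date", "non-positive lag"),
    n = c(sum(missing_date), sum(nonpos))
  )
  out
}

#' Quantile summary of time to onset
#'
#' Quantiles use linear interpolation between order statistics (the type-7
#' convention, R's default). Defaults report the quartiles — the median
#' onset and the interquartile range of the latency distribution.
#'
#' @param records Onset tibble from [extract_onset()] (or any tibble with
#'   a `days` column).
#' @param probabilities Quantile probabilities.
#' @return A one-row tibble: `n_used`, `n_excluded`, `q1_days`,
#'   `median_days`, `q3_days`, plus a `quantiles` list-column with the full
#'   requested table.
#' @export
summarize_onset <- function(records, probabilities = c(0.25, 0.5, 0.75)) {
  if (nrow(records) == 0) abort("no onset records to summarize")
  excl <- attr(records, "exclusions")
  n_excluded <- if (is.null(excl)) 0L else sum(excl$n)
  qs <- quantile(records$days, probs = probabilities, type = 7, names = FALSE)
  qtab <- tibble(probability = probabilities, days = qs)
  grab <- function(p) {
    i <- which(abs(probabilities - p) < 1e-12)
    if (length(i) == 1) qs[i] else NA_real_
  }
  tibble(
    n_used = nrow(records),
    n_excluded = n_excluded,
    q1_days = grab(0.25),
    median_days = grab(0.5),
    q3_days = grab(0.75),
    quantiles = list(qtab)
  )
}

#' Cumulative-incidence step function of onset times
#'
#' The empirical CDF of the onset lags: the fraction of events having
#' occurred by each distinct day value; its final value is exactly 1.
#'
#' @param records Onset tibble from [extract_onset()].
#' @return A tibble with columns `days` (sorted distinct values) and
#'   `cum_incidence`, non-decreasing and ending at 1.
#' @export
onset_curve <- function(records) {
  if (nrow(records) == 0) abort("no onset records")
  n <- nrow(records)
  days <- sort(unique(records$days))
  counts <- as.integer(table(factor(records$days, levels = days)))
  tibble(days = days, cum_incidence = cumsum(counts) / n)
}
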