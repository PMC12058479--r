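#' Baseline characteristics of an event-report series
#'
#' The descriptive "Table 1" of a case series: total count, age and weight
#' as mean and sample standard deviation (denominator n - 1), sex and
#' outcome counts with percentages, and country counts. Percentages are
#' `100 * count / n_total` rounded half-up to two decimals. Each report
#' contributes a single outcome category — its most serious one, by the
#' severity order of [outcome_levels()] (death first) — so outcome counts
#' sum to the total.
#'
#' @param rs A cleaned, event-filtered [report_set].
#' @return A list of class `baseline_summary`: `n_total`, `age`
#'   (`mean`, `sd`), `weight` (`mean`, `sd`), `sex`, `outcome`, `country`
#'   (tibbles with `count` and `pct`).
#' @export
baseline_table <- function(rs) {
  stopifnot(is_report_set(rs))
  n <- n_reports(rs)
  if (n == 0) abort("empty report set")

  cat_tbl <- function(values, levels = NULL) {
    tb <- tibble(value = values) |>
      dplyr::count(.data$value, name = "count") |>
      dplyr::mutate(pct = round_half_up(100 * .data$count / n, 2))
    if (!is.null(levels)) {
      tb <- tb |>
        dplyr::mutate(value = factor(.data$value, levels = levels)) |>
        dplyr::arrange(.data$value) |>
        dplyr::mutate(value = as.character(.data$value))
    } else {
      tb <- dplyr::arrange(tb, dplyr::desc(.data$count))
    }
    tb
  }

  worst <- rs$outcomes |>
    dplyr::mutate(rank = match(.data$outcome, outcome_levels())) |>
    dplyr::summarise(outcome = outcome_levels()[min(.data$rank)],
                     .by = "report_id")

  age <- rs$reports$age_years
  wt <- rs$reports$weight_kg
  structure(
    list(
      n_total = n,
      age = list(mean = mean(age, na.rm = TRUE),
                 sd = if (sum(!is.na(age)) > 1) sd(age, na.rm = TRUE) else 0),
      weight = list(mean = mean(wt, na.rm = TRUE),
                    sd = if (sum(!is.na(wt)) > 1) sd(wt, na.rm = TRUE) else 0),
      sex = cat_tbl(rs$reports$sex, c("female", "male", "unknown")),
      outcome = cat_tbl(worst$outcome, outcome_levels()),
      country = cat_tbl(rs$reports$country)
    ),
    class = "baseline_summary"
  )
}

#' @export
print.baseline_summary <- function(x, ...) {
  cat("<baseline_summary> n =", x$n_total, "\n")
  cat(sprintf("  age:    %.2f +/- %.2f years\n", x$age$mean, x$age$sd))
  cat(sprintf("  weight: %.2f +/- %.2f kg\n", x$weight$mean, x$weight$sd))
  cat("  sex:\n")
  print(as.data.frame(x$sex), row.names = FALSE)
  cat("  outcome (most serious per report):\n")
  print(as.data.frame(x$outcome), row.names = FALSE)
  invisible(x)
}

#' Yearly report counts
#'
#' Counts reports per calendar year, zero-filled across the configured
#' range so trend plots have a complete axis.
#'
#' @param rs A [report_set].
#' @param year_range `c(first, last)`, or `NULL` to span the observed years.
#' @return A tibble with columns `year` and `n`.
#' @export
yearly_counts <- function(rs, year_range = NULL) {
  stopifnot(is_report_set(rs))
  yrs <- rs$reports$report_year
  if (is.null(year_range)) {
    if (length(yrs) == 0) return(tibble(year = integer(), n = integer()))
    year_range <- range(yrs, na.rm = TRUE)
  }
  grid <- tibble(year = seq(year_range[1], year_range[2]))
  counts <- tibble(year = yrs) |> dplyr::count(.data$year)
  grid |>
    dplyr::left_join(counts, by = "year") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Age pyramid counts by sex
#'
#' Tabulates reports into half-open age bins `[0,w)`, `[w,2w)`, ... per
#' sex, for pyramid plots of the case series' age structure. An exact
#' multiple of the bin width falls in the bin it opens (age 65 is in
#' `[65,70)`).
#'
#' @param rs A [report_set] with complete demographics.
#' @param bin_width Bin width in years (default 5).
#' @return A tibble with columns `age_bin` (label), `bin_start`, `sex`,
#'   `n`, covering every bin-sex combination up to the oldest observed bin.
#' @export
age_pyramid <- function(rs, bin_width = 5) {
  stopifnot(is_report_set(rs))
  dat <- rs$reports |>
    dplyr::filter(!is.na(.data$age_years), .data$sex %in% c("female", "male"))
  if (nrow(dat) == 0) {
    return(tibble(age_bin = character(), bin_start = double(),
                  sex = character(), n = integer()))
  }
  dat <- dplyr::mutate(dat,
                       bin_start = floor(.data$age_years / bin_width) * bin_width)
  starts <- seq(0, max(dat$bin_start), by = bin_width)
  grid <- tidyr::expand_grid(bin_start = starts, sex = c("female", "male"))
  counts <- dat |> dplyr::count(.data$bin_start, .data$sex)
  grid |>
    dplyr::left_join(counts, by = c("bin_start", "sex")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  age_bin = sprintf("[%g,%g)", .data$bin_start,
                                    .data$bin_start + bin_width)) |>
    dplyr::relocate("age_bin")
}

#' Round half away from zero
#'
#' Decimal rounding with the half-up convention used for printed
#' percentages (R's `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
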