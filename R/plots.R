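#' Plot helpers for pipeline outputs
#'
#' Thin ggplot2 layers over the plot-ready tables the pipeline emits;
#' publication styling is left to the caller.
#'
#' @param stats A tibble from [ror_stats()] (for `plot_volcano()`).
#' @param criteria Screening thresholds drawn as reference lines.
#' @return A ggplot object.
#' @export
plot_volcano <- function(stats, criteria = signal_criteria()) {
  vt <- volcano_table(stats)
  names(vt)[2:3] <- c("x", "y")
  ggplot2::ggplot(vt, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$log10_n_cases)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(criteria$alpha_adj),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = log2(criteria$ror_min),
                        linetype = "dashed") +
    ggplot2::scale_colour_gradient(low = "steelblue", high = "firebrick") +
    ggplot2::labs(x = "log2(ROR)", y = "-log10(adjusted p)",
                  colour = "log10(cases)",
                  title = "Drug-event disproportionality volcano") +
    ggplot2::theme_minimal()
}

#' @rdname plot_volcano
#' @param rs A [report_set] (for `plot_yearly_trend()` and
#'   `plot_age_pyramid()`).
#' @param year_range Passed to [yearly_counts()].
#' @export
plot_yearly_trend <- function(rs, year_range = NULL) {
  yc <- yearly_counts(rs, year_range)
  ggplot2::ggplot(yc, ggplot2::aes(x = .data$year, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "report year", y = "reports",
                  title = "Yearly report counts") +
    ggplot2::theme_minimal()
}

#' @rdname plot_volcano
#' @param bin_width Passed to [age_pyramid()].
#' @export
plot_age_pyramid <- function(rs, bin_width = 5) {
  ap <- age_pyramid(rs, bin_width) |>
    dplyr::mutate(n_signed = ifelse(.data$sex == "male", -.data$n, .data$n))
  ggplot2::ggplot(ap, ggplot2::aes(x = .data$bin_start, y = .data$n_signed,
                                   fill = .data$sex)) +
    ggplot2::geom_col(orientation = "x") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "age (years)", y = "reports (male left, female right)",
                  title = "Age pyramid of the case series") +
    ggplot2::theme_minimal()
}

#' @rdname plot_volcano
#' @param records Onset records from [extract_onset()] (for
#'   `plot_onset_curve()`).
#' @export
plot_onset_curve <- function(records) {
  cc <- onset_curve(records)
  ggplot2::ggplot(cc, ggplot2::aes(x = .data$days, y = .data$cum_incidence)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "days from therapy start", y = "cumulative incidence",
                  title = "Cumulative incidence of event onset") +
    ggplot2::theme_minimal()
}
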