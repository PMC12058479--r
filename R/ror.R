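#' Reporting odds ratio with log-symmetric Wald interval
#'
#' The disproportionality statistic of the case/non-case design: for a 2x2
#' table with cells `a` (event, drug), `b` (non-event, drug), `c` (event,
#' no drug), `d` (non-event, no drug),
#' \deqn{ROR = \frac{a/c}{b/d} = \frac{ad}{bc},}
#' with the 95% confidence interval
#' \deqn{\exp\big(\ln ROR \pm z_{1-\alpha/2}\sqrt{1/a + 1/b + 1/c + 1/d}\big).}
#' The interval is log-symmetric: the point estimate is the geometric mean
#' of its bounds (see [point_from_ci()]).
#'
#' `ror_stats()` computes ROR, CI, a two-sided Fisher exact p
#' ([fisher_exact_p()], always on the uncorrected counts) and its
#' Bonferroni adjustment for every row of a contingency-table tibble.
#'
#' @param tables Tibble with columns `drug`, `a`, `b`, `c`, `d` (from
#'   [contingency_tables()]).
#' @param zero_policy `"haldane"` (default) adds 0.5 to *all four* cells of
#'   a table containing a zero before computing ROR and CI
#'   (Haldane–Anscombe); `"strict"` raises an error naming the drug. The
#'   `zero_corrected` flag marks rows where the correction fired.
#' @param conf_level Confidence level of the Wald interval.
#' @param m Number of tests for the Bonferroni adjustment. Default: the
#'   number of drugs in `tables` with more than `min_cases_m` case reports
#'   (the set actually screened); recorded in the `m` attribute of the
#'   result.
#' @param min_cases_m Case-count threshold defining the tested family when
#'   `m` is not given.
#' @return A tibble with columns `drug`, `n_cases`, `a`:`d`, `ror`,
#'   `ci_lower`, `ci_upper`, `p_raw`, `p_adj`, `zero_corrected`, carrying
#'   attribute `m`.
#' @export
ror_stats <- function(tables, zero_policy = c("haldane", "strict"),
                      conf_level = 0.95, m = NULL, min_cases_m = 100) {
  zero_policy <- rlang::arg_match(zero_policy)
  stopifnot(all(c("drug", "a", "b", "c", "d") %in% names(tables)))
  # the conventional 1.96 at the default level, matching the CI formula as
  # written in the pharmacovigilance literature
  z <- if (identical(conf_level, 0.95)) 1.96 else qnorm(1 - (1 - conf_level) / 2)

  a <- tables$a; b <- tables$b; c <- tables$c; d <- tables$d
  if (any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != floor(c(a, b, c, d)))) {
    abort("contingency cells must be non-negative integers")
  }
  has_zero <- (a == 0) | (b == 0) | (c == 0) | (d == 0)
  if (zero_policy == "strict" && any(has_zero)) {
    abort(paste0("zero cell in 2x2 table for drug(s): ",
                 paste(tables$drug[has_zero], collapse = ", ")))
  }
  shift <- ifelse(has_zero, 0.5, 0)
  aa <- a + shift; bb <- b + shift; cc <- c + shift; dd <- d + shift

  log_ror <- log(aa) - log(cc) - log(bb) + log(dd)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  p_raw <- fisher_exact_p(a, b, c, d)

  out <- tibble(
    drug = tables$drug, n_cases = as.integer(a),
    a = as.integer(a), b = as.integer(b),
    c = as.integer(c), d = as.integer(d),
    ror = exp(log_ror),
    ci_lower = exp(log_ror - z * se),
    ci_upper = exp(log_ror + z * se),
    p_raw = p_raw,
    zero_corrected = has_zero
  )
  # the adjustment family is the screened subset (drugs with enough cases);
  # drugs outside it still get a capped adjusted p so columns are complete
  if (is.null(m)) m <- sum(out$n_cases > min_cases_m)
  m <- max(m, 1L)
  out$p_adj <- adjust_pvalues(out$p_raw, m)
  attr(out, "m") <- m
  out
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p_raw)`, order-preserving in `p_raw`.
#'
#' @param p Numeric vector of raw p-values in `[0,1]`.
#' @param m Number of tests; must be at least `length(p)` is *not*
#'   required — `m` is the size of the tested family, which may exceed the
#'   vector supplied.
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p, m) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  if (m < 1) abort("m must be a positive count")
  pmin(1, m * p)
}

#' Recover the ROR point estimate from its interval bounds
#'
#' Because the Wald interval is symmetric on the log scale, the point
#' estimate equals the geometric mean of the bounds:
#' `exp((log(lower) + log(upper)) / 2)`. Used to validate printed results
#' and the internal consistency of computed statistics.
#'
#' @param ci_lower,ci_upper Positive interval bounds, `ci_lower <= ci_upper`.
#' @return The implied point estimate.
#' @examples
#' point_from_ci(12.51, 15.48) # 13.92: alendronic acid's printed interval
#' @export
point_from_ci <- function(ci_lower, ci_upper) {
  if (any(ci_lower <= 0) || any(ci_upper <= 0)) {
    abort("interval bounds must be positive")
  }
  if (any(ci_lower > ci_upper)) {
    abort("ci_lower must not exceed ci_upper")
  }
  exp((log(ci_lower) + log(ci_upper)) / 2)
}

#' Two-sided Fisher exact p for 2x2 tables
#'
#' The two-sided p-value is the total hypergeometric probability of all
#' tables with the observed margins whose probability does not exceed that
#' of the observed table (with the customary `1 + 1e-7` relative slack for
#' floating-point ties). Probabilities are accumulated from log-space
#' hypergeometric masses, so tables with margins in the millions are exact
#' and never overflow. Vectorized over tables.
#'
#' @param a,b,c,d Non-negative integer cell counts (event-with-drug,
#'   non-event-with-drug, event-without-drug, non-event-without-drug).
#' @return Numeric vector of two-sided p-values.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) abort("cell counts must be non-negative")
  purrr::pmap_dbl(list(a, b, c, d), fisher_p_one)
}

fisher_p_one <- function(a, b, c, d) {
  m1 <- a + b   # drug margin
  m2 <- a + c   # event margin
  n  <- a + b + c + d
  lo <- max(0, m1 + m2 - n)
  hi <- min(m1, m2)
  k <- lo:hi
  logp <- dhyper(k, m2, n - m2, m1, log = TRUE)
  obs <- logp[k == a]
  min(1, sum(exp(logp[logp <= obs + log(1 + 1e-7)])))
}

#' Signal screening rule
#'
#' `signal_criteria()` bundles the thresholds of the disproportionality
#' screen; `screen_signals()` applies them with *strict* inequalities: a
#' drug is flagged when `n_cases > min_cases`, `ror > ror_min`,
#' `ci_lower > ci_lower_min` and `p_adj < alpha_adj`.
#'
#' The weaker univariate *candidate* rule that feeds the LASSO stage
#' (significance and interval bound only, no ROR magnitude threshold) is
#' exposed as [candidate_drugs()].
#'
#' @param min_cases Case-count threshold (flag requires strictly more).
#' @param ror_min ROR threshold (strictly exceeded).
#' @param ci_lower_min Threshold on the lower 95% bound (strictly exceeded).
#' @param alpha_adj Level for the Bonferroni-adjusted p.
#' @return `signal_criteria()`: a list of thresholds. `screen_signals()`:
#'   the stats tibble with a logical `flagged` column.
#' @export
signal_criteria <- function(min_cases = 100, ror_min = 3,
                            ci_lower_min = 1, alpha_adj = 0.01) {
  if (any(c(min_cases, ror_min, ci_lower_min, alpha_adj) <= 0)) {
    abort("all screening thresholds must be strictly positive")
  }
  list(min_cases = min_cases, ror_min = ror_min,
       ci_lower_min = ci_lower_min, alpha_adj = alpha_adj)
}

#' @rdname signal_criteria
#' @param stats A tibble from [ror_stats()] (with `p_adj` populated).
#' @param criteria A [signal_criteria()] list.
#' @export
screen_signals <- function(stats, criteria = signal_criteria()) {
  stopifnot(all(c("n_cases", "ror", "ci_lower", "p_adj") %in% names(stats)))
  dplyr::mutate(
    stats,
    flagged = .data$n_cases > criteria$min_cases &
      .data$ror > criteria$ror_min &
      .data$ci_lower > criteria$ci_lower_min &
      .data$p_adj < criteria$alpha_adj
  )
}

#' @rdname signal_criteria
#' @param min_cases_cand Case-count threshold of the candidate rule.
#' @param alpha_cand Adjusted-p level of the candidate rule.
#' @return `candidate_drugs()`: character vector of drugs passing the
#'   univariate candidate screen.
#' @export
candidate_drugs <- function(stats, min_cases_cand = 100, alpha_cand = 0.01) {
  stats |>
    dplyr::filter(.data$n_cases > min_cases_cand,
                  .data$ci_lower > 1,
                  .data$p_adj < alpha_cand) |>
    dplyr::pull("drug")
}

#' Volcano-plot table
#'
#' Plot-ready coordinates for the drug-screening volcano: effect size
#' `log2(ROR)` on the x-axis, significance `-log10(p_adj)` on the y-axis
#' (with `p_adj` floored at `1e-300` so zero p-values map to 300), and
#' `log10(n_cases)` as the colour value. Logarithm bases are configurable
#' and written into the column names.
#'
#' @param stats A tibble from [ror_stats()].
#' @param base_x Base of the effect-size logarithm (default 2).
#' @param base_y Base of the significance logarithm (default 10).
#' @return A tibble with columns `drug`, `log<base_x>_ror`,
#'   `neglog<base_y>_p_adj`, `log10_n_cases`.
#' @export
volcano_table <- function(stats, base_x = 2, base_y = 10) {
  stopifnot(all(c("drug", "ror", "p_adj", "n_cases") %in% names(stats)))
  out <- tibble(
    drug = stats$drug,
    x = log(stats$ror, base = base_x),
    y = -log(pmax(stats$p_adj, 1e-300), base = base_y),
    log10_n_cases = log10(pmax(stats$n_cases, 1))
  )
  names(out)[2] <- paste0("log", base_x, "_ror")
  names(out)[3] <- paste0("neglog", base_y, "_p_adj")
  out
}
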