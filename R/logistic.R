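#' Multivariate logistic risk model
#'
#' Maximum-likelihood logistic regression of the event indicator on the
#' candidate drug exposures and demographic covariates, fitted by
#' iteratively reweighted least squares. Standard errors come from the
#' inverse observed information (which equals the expected information
#' under the canonical logit link); Wald 95% intervals are
#' `exp(coef +/- 1.96 * SE)` and p-values use the normal approximation.
#' The Bonferroni adjustment spans the drug terms only — the demographic
#' adjustment covariates are not part of the screened family and keep
#' their raw p. A drug term with `p_adj < 0.01` is flagged as an
#' independent risk factor.
#'
#' Collinear columns are dropped with a warning before fitting. Complete
#' separation is flagged per column (|coef| > 15 with an exploding SE);
#' the fit is still returned.
#'
#' @param dm Design tibble from [build_design_matrix()]; drug columns may
#'   be restricted to a LASSO selection first (see [select_columns()]).
#' @param tol Convergence tolerance on the score max-norm.
#' @param max_iter Maximum IRLS iterations.
#' @param alpha_flag Adjusted-p level for the independent-risk-factor flag.
#' @return An object of class `logistic_fit` with [tidy()], [glance()] and
#'   [augment()] methods: coefficient table (`term`, `estimate`,
#'   `std_error`, `or`, `or_low`, `or_high`, `p_raw`, `p_adj`, `is_drug`,
#'   `separated`, `flagged_independent`), `converged`, `n_iter`,
#'   `loglik`, fitted probabilities.
#' @export
fit_logistic <- function(dm, tol = 1e-8, max_iter = 100, alpha_flag = 0.01) {
  pieces <- dm_pieces(dm)
  y <- pieces$y
  x <- cbind("(Intercept)" = 1, pieces$x)

  # drop collinear columns (never the intercept)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    drop_idx <- qrx$pivot[seq(qrx$rank + 1, ncol(x))]
    warn(paste0("dropping collinear column(s): ",
                paste(colnames(x)[drop_idx], collapse = ", ")))
    x <- x[, -drop_idx, drop = FALSE]
  }

  ctrl <- stats::glm.control(epsilon = 1e-12, maxit = max_iter)
  fit <- suppressWarnings(
    stats::glm.fit(x, y, family = binomial(), control = ctrl))
  beta <- fit$coefficients
  p <- fit$fitted.values
  score <- as.vector(crossprod(x, y - p))
  converged <- max(abs(score)) < tol && fit$converged

  w <- p * (1 - p)
  info <- crossprod(x * sqrt(w))
  vc <- tryCatch(solve(info), error = function(e) {
    diag(Inf, ncol(x), dimnames = list(colnames(x), colnames(x)))
  })
  se <- sqrt(diag(vc))
  separated <- abs(beta) > 15 & se > 10

  z <- beta / se
  p_raw <- 2 * pnorm(-abs(z))
  is_drug <- colnames(x) %in% pieces$drug_cols
  m_drug <- max(sum(is_drug), 1L)
  p_adj <- ifelse(is_drug, pmin(1, m_drug * p_raw), p_raw)

  coefs <- tibble(
    term = colnames(x),
    estimate = unname(beta),
    std_error = unname(se),
    or = exp(unname(beta)),
    or_low = exp(unname(beta - 1.96 * se)),
    or_high = exp(unname(beta + 1.96 * se)),
    p_raw = unname(p_raw),
    p_adj = unname(p_adj),
    is_drug = is_drug,
    separated = unname(separated),
    flagged_independent = is_drug & p_adj < alpha_flag
  )
  loglik <- sum(y * log(p) + (1 - y) * log1p(-p))

  structure(
    list(coefficients = coefs, converged = converged, n_iter = fit$iter,
         loglik = loglik, fitted = p, y = y, n = length(y),
         m_drug = m_drug, max_score = max(abs(score))),
    class = "logistic_fit"
  )
}

#' Restrict a design matrix to a drug selection
#'
#' Keeps the identifier, outcome, demographic columns and the given drug
#' columns — the bridge from the LASSO selection to the multivariate fit.
#'
#' @param dm Design tibble from [build_design_matrix()].
#' @param drugs Character vector of drug columns to keep.
#' @return The restricted design tibble (attributes updated).
#' @export
select_columns <- function(dm, drugs) {
  drug_cols <- attr(dm, "drug_cols")
  keep <- intersect(drug_cols, drugs)
  if (length(keep) == 0) abort("selection keeps no drug column")
  out <- dm[, c("report_id", "event", keep,
                "age_years", "weight_kg", "sex_female")]
  attr(out, "drug_cols") <- keep
  attr(out, "demog_cols") <- c("age_years", "weight_kg", "sex_female")
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> n = ", x$n, ", logLik = ",
      format(x$loglik, digits = 6), ", ",
      ifelse(x$converged, "converged", "NOT converged"),
      " in ", x$n_iter, " iterations\n", sep = "")
  print(x$coefficients, n = 20)
  invisible(x)
}

#' @export
tidy.logistic_fit <- function(x, ...) x$coefficients

#' @export
glance.logistic_fit <- function(x, ...) {
  tibble(n = x$n, loglik = x$loglik, converged = x$converged,
         n_iter = x$n_iter,
         n_independent = sum(x$coefficients$flagged_independent))
}

#' @export
augment.logistic_fit <- function(x, ...) {
  tibble(.fitted = x$fitted, event = x$y)
}
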