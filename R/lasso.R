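#' Cross-validated LASSO logistic screening of candidate drugs
#'
#' L1-penalized logistic regression over the candidate drug indicators,
#' used as the variable-selection stage between the univariate screen and
#' the multivariate model. Drug indicators are penalized; the demographic
#' covariates (and the intercept) are *never* penalized, preserving their
#' role as adjustment variables. Covariates are standardized internally by
#' the solver and coefficients are returned on the original scale.
#'
#' The penalty grid is log-spaced over four decades downward from a
#' data-derived `lambda_max` — the smallest penalty at which every drug
#' coefficient is exactly zero, computed from the Karush–Kuhn–Tucker
#' condition `max_j |<x_j_std, y - p0>| / n` with `p0` fitted from the
#' unpenalized covariates alone. Selection uses `k`-fold cross-validation
#' with outcome-stratified, seeded folds assigned on the canonical row
#' ordering (so permuting input rows changes nothing); the selected
#' `lambda` minimizes mean CV binomial deviance ("lambda.min" rule).
#'
#' @param dm Design tibble from [build_design_matrix()].
#' @param grid_size Number of penalty values on the grid.
#' @param k_folds Number of CV folds (>= 2).
#' @param seed Integer seed for the fold assignment.
#' @return An object of class `lasso_path`: list with `lambda`, `beta`
#'   (coefficients per term and lambda, original scale), `cv_mean_deviance`,
#'   `cv_se`, `selected_lambda`, `selected_drugs`, `drug_cols`,
#'   `demog_cols`, `foldid`. Has [tidy()], [glance()] and [autoplot()]
#'   methods.
#' @export
fit_lasso_logistic <- function(dm, grid_size = 100, k_folds = 10, seed = 1L) {
  if (k_folds < 2) abort("k_folds must be at least 2")
  pieces <- dm_pieces(dm)
  y <- pieces$y
  x <- pieces$x
  n <- length(y)
  pf <- c(rep(1, length(pieces$drug_cols)), rep(0, length(pieces$demog_cols)))

  lambda_max <- lasso_lambda_max(x, y, pieces)
  lambda <- exp(seq(log(lambda_max), log(lambda_max * 1e-4),
                    length.out = grid_size))

  foldid <- stratified_folds(y, k_folds, seed)
  if (any(tapply(y, foldid, function(v) length(unique(v))) < 2)) {
    abort("every fold must contain both outcome classes; reduce k_folds")
  }

  cv <- glmnet::cv.glmnet(
    x, y, family = "binomial", lambda = lambda, foldid = foldid,
    penalty.factor = pf, standardize = TRUE, type.measure = "deviance",
    thresh = 1e-12, maxit = 1e6
  )
  fit <- cv$glmnet.fit
  beta <- as.matrix(rbind(`(Intercept)` = fit$a0, as.matrix(fit$beta)))
  colnames(beta) <- signif(fit$lambda, 6)

  sel_lambda <- cv$lambda.min
  sel_col <- which.min(abs(fit$lambda - sel_lambda))
  drug_beta <- beta[pieces$drug_cols, sel_col]
  structure(
    list(
      lambda = fit$lambda,
      beta = beta,
      cv_mean_deviance = cv$cvm,
      cv_se = cv$cvsd,
      selected_lambda = sel_lambda,
      selected_drugs = names(drug_beta)[drug_beta != 0],
      drug_cols = pieces$drug_cols,
      demog_cols = pieces$demog_cols,
      foldid = foldid,
      n = n
    ),
    class = "lasso_path"
  )
}

# KKT-derived smallest all-zero penalty: restricted fit on the unpenalized
# covariates, then the max absolute standardized-score over drug columns.
lasso_lambda_max <- function(x, y, pieces) {
  n <- length(y)
  xd <- x[, pieces$demog_cols, drop = FALSE]
  p0 <- stats::glm.fit(cbind(1, xd), y, family = binomial())$fitted.values
  xs <- x[, pieces$drug_cols, drop = FALSE]
  mu <- colMeans(xs)
  sdv <- sqrt(colMeans(sweep(xs, 2, mu)^2))
  sdv[sdv == 0] <- 1
  score <- abs(crossprod(sweep(sweep(xs, 2, mu), 2, sdv, "/"), y - p0)) / n
  max(score)
}

# Outcome-stratified fold labels, deterministic given the seed and row order.
stratified_folds <- function(y, k, seed) {
  foldid <- integer(length(y))
  rng <- local({
    set.seed(seed)
    list(one = sample(rep_len(seq_len(k), sum(y == 1))),
         zero = sample(rep_len(seq_len(k), sum(y == 0))))
  })
  foldid[y == 1] <- rng$one
  foldid[y == 0] <- rng$zero
  foldid
}

#' @export
print.lasso_path <- function(x, ...) {
  cat("<lasso_path> ", length(x$lambda), " lambda values, ",
      length(x$drug_cols), " penalized drug terms\n", sep = "")
  cat("  selected lambda: ", format(x$selected_lambda, digits = 4),
      " (", length(x$selected_drugs), " drugs selected)\n", sep = "")
  invisible(x)
}

#' @export
tidy.lasso_path <- function(x, ...) {
  beta <- x$beta
  tibble(
    lambda = rep(x$lambda, each = nrow(beta)),
    term = rep(rownames(beta), times = ncol(beta)),
    estimate = as.vector(beta)
  )
}

#' @export
glance.lasso_path <- function(x, ...) {
  tibble(
    lambda_max = x$lambda[1],
    selected_lambda = x$selected_lambda,
    n_selected = length(x$selected_drugs),
    n_terms = length(x$drug_cols),
    n = x$n
  )
}

#' @export
autoplot.lasso_path <- function(object, ...) {
  dat <- tidy(object) |>
    dplyr::filter(.data$term %in% object$drug_cols)
  ggplot2::ggplot(dat, ggplot2::aes(x = log(.data$lambda),
                                    y = .data$estimate,
                                    group = .data$term,
                                    colour = .data$term)) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = log(object$selected_lambda),
                        linetype = "dashed") +
    ggplot2::labs(x = "log(lambda)", y = "coefficient",
                  title = "LASSO coefficient paths (drug terms)") +
    ggplot2::theme_minimal()
}
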