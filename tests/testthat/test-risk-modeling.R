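test_that("design matrix has one indicator per candidate plus demographics", {
  sim <- simulate_reports(sim_config(
    n_reports = 2000,
    drugs = tibble::tibble(ingredient = c("A", "B"),
                           exposure_probability = c(0.2, 0.2),
                           true_log_or = c(log(3), 0)),
    seed = 3))
  cl <- clean_reports(sim$reports)
  dm <- build_design_matrix(cl, c("A", "B"), "CATARACT")
  expect_named(dm, c("report_id", "event", "A", "B",
                     "age_years", "weight_kg", "sex_female"))
  # indicator sums equal per-drug exposed counts
  ps <- cl$drugs[cl$drugs$role == "primary-suspect", ]
  expect_equal(sum(dm$A), sum(ps$ingredient == "A"))
  expect_equal(sum(dm$B), sum(ps$ingredient == "B"))
  # reports whose suspect drug is not a candidate have all-zero indicators
  other <- dm[!dm$report_id %in% ps$report_id[ps$ingredient %in% c("A", "B")], ]
  expect_true(all(other$A == 0 & other$B == 0))
  # a candidate with no exposed report is dropped with a warning
  expect_warning(dm2 <- build_design_matrix(cl, c("A", "B", "GHOST"),
                                            "CATARACT"), "GHOST")
  expect_named(dm2, names(dm))
})

test_that("IRLS reproduces closed-form logistic fits", {
  # intercept-only: coefficient is the logit of the outcome mean
  dm0 <- mk_dm(data.frame(), data.frame(),
               event = rep(c(1, 0), c(25, 75)))
  attr(dm0, "drug_cols") <- character(0)
  fit0 <- fit_logistic(dm0)
  expect_equal(fit0$coefficients$estimate[1], log(1 / 3), tolerance = 1e-8)

  # single binary covariate: slope is the log odds ratio of the 2x2 table
  a <- 12; b <- 28; c <- 15; d <- 145
  x <- rep(c(1, 1, 0, 0), c(a, b, c, d))
  y <- rep(c(1, 0, 1, 0), c(a, b, c, d))
  dm1 <- mk_dm(data.frame(X = x), NULL, event = y)
  fit1 <- fit_logistic(dm1)
  est <- fit1$coefficients
  expect_equal(est$estimate[est$term == "X"], log(a * d / (b * c)),
               tolerance = 1e-8)
})

test_that("IRLS agrees with a damped-Newton oracle on a random fixture", {
  dm <- mk_logistic_fixture(n = 400, seed = 8)
  fit <- fit_logistic(dm)
  expect_true(fit$converged)
  pieces <- as.matrix(dm[, c(attr(dm, "drug_cols"), attr(dm, "demog_cols"))])
  oracle <- newton_logistic(pieces, dm$event)
  expect_equal(fit$coefficients$estimate, unname(oracle), tolerance = 1e-6)
  # Wald interval is log-symmetric about the odds ratio
  cf <- fit$coefficients
  expect_equal(sqrt(cf$or_low * cf$or_high), cf$or, tolerance = 1e-10)
})

test_that("the LASSO path is null at lambda_max and matches IRLS as lambda vanishes", {
  dm <- mk_logistic_fixture(n = 500, seed = 42)
  lp <- fit_lasso_logistic(dm, grid_size = 60, k_folds = 5, seed = 2)
  drug_cols <- attr(dm, "drug_cols")
  expect_true(all(lp$beta[drug_cols, 1] == 0))
  expect_true(any(lp$beta[drug_cols, ncol(lp$beta)] != 0))
  # at lambda_max * 1e-4 the penalty is negligible: compare with ML fit
  mle <- fit_logistic(dm)$coefficients
  final <- lp$beta[mle$term, ncol(lp$beta)]
  expect_lt(max(abs(unname(final) - mle$estimate)), 1e-4)
})

test_that("LASSO selection is seeded, deterministic and row-order invariant", {
  sim <- simulate_reports(sim_config(
    n_reports = 5000,
    drugs = tibble::tibble(ingredient = sprintf("D%d", 1:6),
                           exposure_probability = 0.08,
                           true_log_or = c(log(4), log(3), 0, 0, 0, 0)),
    seed = 17))
  cl <- clean_reports(sim$reports)
  dm <- build_design_matrix(cl, sprintf("D%d", 1:6), "CATARACT")
  lp1 <- fit_lasso_logistic(dm, grid_size = 40, k_folds = 5, seed = 9)
  lp2 <- fit_lasso_logistic(dm, grid_size = 40, k_folds = 5, seed = 9)
  expect_identical(lp1$beta, lp2$beta)
  expect_identical(lp1$selected_drugs, lp2$selected_drugs)
  # permuting the input report order changes nothing: rows are canonicalized
  perm <- cl
  idx <- sample(nrow(perm$reports))
  perm$reports <- perm$reports[idx, ]
  perm$drugs <- perm$drugs[sample(nrow(perm$drugs)), ]
  perm$reactions <- perm$reactions[sample(nrow(perm$reactions)), ]
  dmp <- build_design_matrix(perm, sprintf("D%d", 1:6), "CATARACT")
  lp3 <- fit_lasso_logistic(dmp, grid_size = 40, k_folds = 5, seed = 9)
  expect_identical(lp1$beta, lp3$beta)
  expect_equal(lp1$selected_lambda, lp3$selected_lambda)
})

test_that("true-signal drugs survive LASSO selection across seeds", {
  true_drugs <- sprintf("S%d", 1:5)
  hits <- 0L
  n_rep <- 5
  for (i in seq_len(n_rep)) {
    sim <- simulate_reports(sim_config(
      n_reports = 20000,
      drugs = dplyr::bind_rows(
        tibble::tibble(ingredient = true_drugs, exposure_probability = 0.03,
                       true_log_or = log(c(3, 4, 6, 10, 14))),
        tibble::tibble(ingredient = sprintf("N%02d", 1:10),
                       exposure_probability = 0.03, true_log_or = 0)),
      seed = 500 + i))
    cl <- clean_reports(sim$reports)
    dm <- build_design_matrix(cl, c(true_drugs, sprintf("N%02d", 1:10)),
                              "CATARACT")
    lp <- fit_lasso_logistic(dm, grid_size = 40, k_folds = 5, seed = i)
    hits <- hits + all(true_drugs %in% lp$selected_drugs)
  }
  expect_gte(hits, n_rep - 1)
})

test_that("tidy, glance and selection helpers expose the fit surface", {
  dm <- mk_logistic_fixture(n = 300, seed = 12)
  fit <- fit_logistic(dm)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "or", "p_adj",
                    "flagged_independent") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n, 300)
  lp <- fit_lasso_logistic(dm, grid_size = 30, k_folds = 5, seed = 1)
  expect_named(glance(lp), c("lambda_max", "selected_lambda", "n_selected",
                             "n_terms", "n"))
  sel <- select_columns(dm, c("D1", "D5"))
  expect_equal(attr(sel, "drug_cols"), c("D1", "D5"))
  expect_named(sel, c("report_id", "event", "D1", "D5",
                      "age_years", "weight_kg", "sex_female"))
})

test_that("AUC equals pairwise concordance and handles degenerate scores", {
  set.seed(3)
  y <- rbinom(200, 1, 0.4)
  score <- round(runif(200), 2)   # induces ties
  expect_equal(roc_auc(score, y), auc_pairwise(score, y), tolerance = 1e-10)
  # perfect separation and all-ties
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), "both outcome classes")
})

test_that("the ROC curve is monotone and spans (0,0) to (1,1)", {
  set.seed(4)
  y <- rbinom(150, 1, 0.3)
  score <- rnorm(150)
  pts <- roc_points(score, y)
  expect_true(all(diff(pts$tpr) >= 0))
  expect_true(all(diff(pts$fpr) >= 0))
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_equal(pts$fpr[nrow(pts)], 1)
})

test_that("rank-based AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  y <- rbinom(300, 1, 0.35)
  score <- round(rnorm(300), 1)
  ref <- as.numeric(pROC::auc(pROC::roc(y, score, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(score, y), ref, tolerance = 1e-10)
})
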