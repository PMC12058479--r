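test_that("contingency tables match hand counts and share margins", {
  rs <- mk_ten_report_set()
  tabs <- contingency_tables(rs, "CATARACT")
  x <- tabs[tabs$drug == "X", ]
  expect_equal(c(x$a, x$b, x$c, x$d), c(3, 2, 1, 4))
  y <- tabs[tabs$drug == "Y", ]
  expect_equal(c(y$a, y$b, y$c, y$d), c(1, 4, 3, 2))
  expect_equal(unique(tabs$a + tabs$c), 4)
  expect_equal(unique(tabs$b + tabs$d), 6)
  # drug absent from all event reports gets a = 0
  rs2 <- mk_rs(tibble::tibble(report_id = c("E", "N")),
               drugs = tibble::tibble(report_id = c("E", "N"),
                                      name_raw = c("P", "Q")),
               reactions = tibble::tibble(report_id = c("E", "N"),
                                          pt = c("CATARACT", "NAUSEA")))
  t2 <- contingency_tables(rs2, "CATARACT")
  expect_equal(t2$a[t2$drug == "Q"], 0)
  # exclusion list removes event-treatment drugs from the output
  t3 <- contingency_tables(rs, "CATARACT", exclude_drugs = "X")
  expect_false("X" %in% t3$drug)
})

test_that("ROR and its Wald interval follow the 2x2 formulas", {
  tabs <- tibble::tibble(drug = c("S", "T"),
                         a = c(10, 20), b = c(10, 80),
                         c = c(10, 10), d = c(10, 890))
  st <- ror_stats(tabs)
  # symmetric table: ROR 1, CI exp(+/- 1.96 * sqrt(0.4))
  expect_equal(st$ror[1], 1)
  expect_equal(st$ci_lower[1], exp(-1.96 * sqrt(0.4)), tolerance = 1e-10)
  expect_equal(st$ci_upper[1], exp(+1.96 * sqrt(0.4)), tolerance = 1e-10)
  # hand-evaluated table: ad/bc = 17800/800
  expect_equal(st$ror[2], 22.25)
  expect_equal(st$ci_lower[2], 10.07, tolerance = 1e-3)
  expect_equal(st$ci_upper[2], 49.17, tolerance = 1e-3)
  expect_false(any(st$zero_corrected))
})

test_that("zero cells obey the chosen policy", {
  tabs <- tibble::tibble(drug = "Z", a = 0, b = 10, c = 5, d = 100)
  st <- ror_stats(tabs, zero_policy = "haldane")
  expect_true(st$zero_corrected)
  expect_equal(st$ror, (0.5 / 5.5) / (10.5 / 100.5), tolerance = 1e-12)
  # Fisher p stays on the uncorrected counts
  expect_equal(st$p_raw, fisher_enum_p(0, 10, 5, 100), tolerance = 1e-9)
  expect_error(ror_stats(tabs, zero_policy = "strict"), "Z")
})

test_that("the point estimate is recovered from printed interval bounds", {
  expect_equal(round_half_up(point_from_ci(12.51, 15.48), 2), 13.92)
  expect_equal(point_from_ci(7, 7), 7)
  expect_error(point_from_ci(-1, 2), "positive")
  expect_error(point_from_ci(3, 2), "exceed")
})

test_that("Fisher exact p matches hand enumerations", {
  expect_equal(fisher_exact_p(1, 1, 1, 1), 1.0)
  expect_equal(fisher_exact_p(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact_p(0, 10, 10, 0), 2 / choose(20, 10),
               tolerance = 1e-12)
})

test_that("Fisher p agrees with stats::fisher.test on random tables", {
  set.seed(7)
  for (i in 1:50) {
    cells <- rpois(4, 8)
    if (sum(cells) == 0) next
    ours <- fisher_exact_p(cells[1], cells[2], cells[3], cells[4])
    ref <- stats::fisher.test(matrix(cells, 2))$p.value
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("Fisher p never overflows on million-scale margins", {
  p <- fisher_exact_p(500, 5000, 20000, 2e6)
  expect_true(is.finite(p) && p >= 0 && p <= 1)
  expect_lt(p, 1e-100)  # wildly disproportionate table
})

test_that("Bonferroni adjustment multiplies, caps and preserves order", {
  expect_equal(adjust_pvalues(0.001, 5), 0.005)
  expect_equal(adjust_pvalues(0.5, 10), 1.0)
  set.seed(1)
  p <- runif(30)
  expect_true(all(diff(adjust_pvalues(p, 40)[order(p)]) >= 0))
  expect_error(adjust_pvalues(1.2, 3), "\\[0, 1\\]")
})

test_that("signal screening applies strict inequalities on every criterion", {
  st <- tibble::tibble(
    drug = c("pass", "ror_at_3", "n_at_100", "ci_at_1", "p_at_alpha"),
    n_cases = c(150L, 150L, 100L, 150L, 150L),
    ror = c(5, 3.0, 5, 5, 5),
    ci_lower = c(2, 2, 2, 1.0, 2),
    p_adj = c(0.001, 0.001, 0.001, 0.001, 0.01)
  )
  out <- screen_signals(st, signal_criteria())
  expect_equal(out$drug[out$flagged], "pass")
})

test_that("volcano coordinates use the documented bases and p floor", {
  st <- tibble::tibble(drug = c("a", "b", "c"),
                       ror = c(1, 4, 10),
                       p_adj = c(1, 0.01, 0),
                       n_cases = c(10L, 100L, 1000L))
  v <- volcano_table(st)
  expect_named(v, c("drug", "log2_ror", "neglog10_p_adj", "log10_n_cases"))
  expect_equal(v$log2_ror[1], 0)
  expect_equal(v$neglog10_p_adj[1], 0)
  expect_equal(v$neglog10_p_adj[3], 300)   # p floored at 1e-300
  expect_equal(v$log10_n_cases, c(1, 2, 3))
})

test_that("ROR equals ad/bc and the CI is log-symmetric on random tables", {
  set.seed(11)
  n_tab <- 1000
  cells <- matrix(sample(1:500, 4 * n_tab, replace = TRUE), ncol = 4)
  tabs <- tibble::tibble(drug = sprintf("d%04d", seq_len(n_tab)),
                         a = cells[, 1], b = cells[, 2],
                         c = cells[, 3], d = cells[, 4])
  st <- ror_stats(tabs, m = n_tab)
  direct <- cells[, 1] * cells[, 4] / (cells[, 2] * cells[, 3])
  expect_equal(st$ror, direct, tolerance = 1e-12)
  expect_equal(point_from_ci(st$ci_lower, st$ci_upper), st$ror,
               tolerance = 1e-12)
  expect_true(all(st$ci_lower <= st$ror & st$ror <= st$ci_upper))
  expect_true(all(st$p_adj >= st$p_raw))
})

test_that("with fixed margins the ROR increases strictly in a", {
  m1 <- 60; m2 <- 100; n <- 1000
  a <- 5:55
  tabs <- tibble::tibble(drug = sprintf("a%02d", a),
                         a = a, b = m1 - a, c = m2 - a,
                         d = n - m1 - m2 + a)
  st <- ror_stats(tabs, m = length(a))
  expect_true(all(diff(st$ror[order(tabs$a)]) > 0))
})
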