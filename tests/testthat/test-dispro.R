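# Published point estimates and 95% bounds for the incretin/GERD analysis,
# keyed by fixture row name: ror, ror_lo, ror_hi, ic, ic_lo, ic_hi (2 d.p.).
published_signals <- list(
  "GLP-1-RAs (ALL)" = c(5.61, 3.95, 7.96, 2.17, 1.66, 2.67),
  "dulaglutide"     = c(3.08, 0.41, 23.04, 0.56, -1.57, 2.70),
  "exenatide"       = c(11.08, 6.75, 18.18, 2.70, 2.00, 3.41),
  "liraglutide"     = c(3.39, 2.00, 5.74, 1.49, 0.74, 2.24),
  "lixisenatide"    = c(5.32, 0.69, 41.28, 0.71, -1.48, 2.91),
  "DPP-4-Is (ALL)"  = c(0.54, 0.37, 0.77, -0.81, -1.34, -0.29),
  "alogliptin"      = c(0.17, 0.02, 1.20, -1.77, -3.82, 0.28),
  "linagliptin"     = c(0.71, 0.26, 1.91, -0.40, -1.71, 0.90),
  "sitagliptin"     = c(0.80, 0.48, 1.31, -0.30, -1.01, 0.41),
  "trelagliptin"    = c(3.25, 0.43, 24.39, 0.58, -1.56, 2.72),
  "vildagliptin"    = c(0.44, 0.23, 0.85, -1.07, -2.00, -0.15),
  "GLP-1-RAs (ALL) | Vomiting" = c(6.73, 4.36, 10.39, 2.32, 1.69, 2.94),
  "GLP-1-RAs (ALL) | Nausea" = c(5.37, 3.26, 8.85, 2.02, 1.31, 2.73),
  "GLP-1-RAs (ALL) | Impaired gastric emptying" = c(44.93, 4.07, 496.40, 0.94, -1.57, 3.44),
  "GLP-1-RAs (ALL) | Oesophageal ulcer" = c(5.28, 0.70, 39.79, 0.72, -1.42, 2.87),
  "GLP-1-RAs (ALL) | Gastrooesophageal reflux disease" = c(3.90, 0.53, 28.98, 0.65, -1.48, 2.77),
  "GLP-1-RAs (ALL) | Dysphagia" = c(3.33, 0.45, 24.53, 0.60, -1.52, 2.71),
  "GLP-1-RAs (ALL) | Abdominal distension" = c(2.81, 0.38, 20.58, 0.54, -1.56, 2.64),
  "DPP-4-Is (ALL) | Vomiting" = c(0.39, 0.22, 0.70, -1.21, -2.03, -0.39),
  "DPP-4-Is (ALL) | Nausea" = c(0.32, 0.17, 0.63, -1.44, -2.37, -0.52),
  "DPP-4-Is (ALL) | Gastrooesophageal reflux disease" = c(3.63, 1.44, 9.15, 1.17, -0.06, 2.41),
  "DPP-4-Is (ALL) | Dysphagia" = c(2.37, 0.90, 6.23, 0.80, -0.49, 2.10),
  "DPP-4-Is (ALL) | Abdominal distension" = c(0.34, 0.05, 2.49, -0.95, -3.05, 1.15),
  "DPP-4-Is (ALL) | Erosive oesophagitis" = c(0.45, 0.06, 3.35, -0.67, -2.79, 1.44),
  "DPP-4-Is (ALL) | Dyspepsia" = c(0.25, 0.03, 1.79, -1.29, -3.37, 0.80))

test_that("every published ROR and IC (with bounds) reproduces at 2 d.p.", {
  tabs <- incretin_gerd_tables()
  for (nm in names(published_signals)) {
    fit <- dispro(tabs[[nm]])
    got <- round_half_up(c(fit$ror, fit$ror_lo, fit$ror_hi,
                           fit$ic, fit$ic_lo, fit$ic_hi), 2)
    expect_equal(got, published_signals[[nm]], info = nm)
  }
})

test_that("zero-cell rows are undefined (dash convention), IC non-evaluable", {
  tabs <- incretin_gerd_tables()
  for (nm in c("anagliptin", "omarigliptin", "saxagliptin", "teneligliptin")) {
    fit <- dispro(tabs[[nm]])
    expect_true(is.na(fit$ror), info = nm)
    expect_true(is.na(fit$signal_value), info = nm)
    expect_false(fit$evaluable, info = nm)
    expect_false(fit$signal_ror || fit$signal_ic ||
                   fit$inverse_ror || fit$inverse_ic, info = nm)
  }
})

test_that("PRR and chi-square agree with independent arithmetic", {
  tb <- contingency_table(36, 393, 618, 37840)
  expect_equal(prr(tb), (36 / 429) / (618 / 38458), tolerance = 1e-12)
  expect_equal(round(prr(tb), 3), 5.222)
  # expected-counts oracle: sum (O - E)^2 / E over the four cells
  O <- c(36, 393, 618, 37840)
  rowm <- c(429, 38458); colm <- c(654, 38233); N <- 38887
  E <- outer(rowm, colm) / N
  expect_equal(pearson_chi2(tb), sum((matrix(O, 2, byrow = TRUE) - E)^2 / E),
               tolerance = 1e-10)
  # cross-check against the standard implementation
  expect_equal(pearson_chi2(tb),
               unname(stats::chisq.test(matrix(O, 2, byrow = TRUE),
                                        correct = FALSE)$statistic),
               tolerance = 1e-10)
  expect_equal(pearson_chi2(contingency_table(2, 8, 3, 7), yates = TRUE),
               unname(suppressWarnings(  # small expected counts, by design
                 stats::chisq.test(matrix(c(2, 8, 3, 7), 2, byrow = TRUE),
                                   correct = TRUE))$statistic),
               tolerance = 1e-10)
  # balanced table: independence, zero statistic, PRR 1
  bal <- contingency_table(10, 10, 10, 10)
  expect_equal(pearson_chi2(bal), 0)
  expect_equal(prr(bal), 1)
  expect_equal(ror_ci(bal)$ror, 1)
  # degenerate cases
  expect_equal(prr(contingency_table(0, 10, 5, 100)), 0)
  expect_true(is.na(prr(contingency_table(5, 10, 0, 100))))
  expect_true(pearson_chi2(contingency_table(2, 8, 3, 7), yates = TRUE) <
                pearson_chi2(contingency_table(2, 8, 3, 7)))
})

test_that("IC shrinks to zero under independence and to log2(RRR) for large counts", {
  # observed equals expected under independence at large N
  tb <- contingency_table(100, 900, 900, 8100)
  expect_lt(abs(ic_ci(tb)$ic), 0.05)
  # large-count limit: IC -> log2 of the relative reporting ratio
  k <- 1e6
  tb2 <- contingency_table(4 * k, k, k, k)
  rrr <- tb2$a * tb2$N / (tb2$n1plus * tb2$nplus1)
  expect_equal(ic_ci(tb2)$ic, log2(rrr), tolerance = 1e-3)
})

test_that("ROR is invariant under joint row/column swap and transposition", {
  set.seed(1)
  for (i in 1:25) {
    cells <- sample(1:500, 4)
    tb <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    swapped <- contingency_table(cells[4], cells[3], cells[2], cells[1])
    transposed <- contingency_table(cells[1], cells[3], cells[2], cells[4])
    expect_equal(ror_ci(tb)$ror, ror_ci(swapped)$ror)
    expect_equal(ror_ci(tb)$ror, ror_ci(transposed)$ror)
    # Woolf interval is geometrically symmetric: lo * hi = ror^2
    r <- ror_ci(tb)
    expect_equal(r$lo * r$hi, r$ror^2, tolerance = 1e-9)
  }
})

test_that("increasing a (b, c, d fixed) strictly increases ROR, PRR and IC", {
  set.seed(2)
  for (i in 1:25) {
    cells <- sample(5:300, 4)
    t0 <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    t1 <- contingency_table(cells[1] + 1, cells[2], cells[3], cells[4])
    expect_gt(ror_ci(t1)$ror, ror_ci(t0)$ror)
    expect_gt(prr(t1), prr(t0))
  }
  # the IC also rises with a, in the sparse-table regime (a^2 < bc) where
  # the joint count does not dominate its own margins — adding a joint
  # report also inflates both marginals, so outside that regime even the
  # raw observed/expected ratio can fall
  for (i in 1:25) {
    a <- sample(1:40, 1)
    bc <- sample((a^2 + 1):5000, 2, replace = TRUE)
    t0 <- contingency_table(a, bc[1], bc[2], sample(2000:50000, 1))
    t1 <- contingency_table(a + 1, bc[1], bc[2], t0$d)
    expect_gt(ic_ci(t1)$ic, ic_ci(t0)$ic)
  }
})

test_that("signal value is ln(PRR) + ln(chi-square), undefined where either is", {
  tb <- contingency_table(36, 393, 618, 37840)
  expect_equal(signal_value(tb), log(prr(tb)) + log(pearson_chi2(tb)),
               tolerance = 1e-12)
  expect_true(is.na(signal_value(contingency_table(10, 10, 10, 10))))  # chi2 = 0
  # PRR < 1 with chi2 > 0: defined, ln(PRR) contributes negatively
  tb2 <- contingency_table(5, 500, 100, 1000)
  expect_lt(prr(tb2), 1)
  sv <- signal_value(tb2)
  expect_false(is.na(sv))
  expect_lt(sv, log(pearson_chi2(tb2)))
})

test_that("signal-value comparison uses the strict doubling rule", {
  expect_equal(compare_signal_values(7.26, 3.46), "a_dominant")
  expect_equal(compare_signal_values(6.33, 4.71), "no_difference")
  expect_equal(compare_signal_values(5.0, 5.0), "no_difference")
  expect_equal(compare_signal_values(3.46, 7.26), "b_dominant")
  expect_equal(compare_signal_values(NA, 3), "not_evaluable")
  # boundary: exactly double is not dominance (strict inequality)
  expect_equal(compare_signal_values(4, 2), "no_difference")
})

test_that("detection flags follow the interval criteria", {
  tabs <- incretin_gerd_tables()
  glp <- dispro(tabs[["GLP-1-RAs (ALL)"]])
  expect_true(glp$signal_ror && glp$signal_ic && glp$signal_both)
  ige <- dispro(tabs[["GLP-1-RAs (ALL) | Impaired gastric emptying"]])
  expect_true(ige$signal_ror)
  expect_false(ige$signal_ic)
  dpp <- dispro(tabs[["DPP-4-Is (ALL)"]])
  expect_true(dpp$inverse_ror && dpp$inverse_ic)
  expect_false(dpp$signal_ror || dpp$signal_ic)
})

test_that("the dispro object supports the standard model-object verbs", {
  fit <- dispro(table_from_marginals(36, 429, 654, 38887, target = "glp1"))
  expect_s3_class(fit, "dispro")
  expect_named(coef(fit), c("ror", "prr", "chi2", "ic", "signal_value"))
  ci <- confint(fit)
  expect_equal(dim(ci), c(2, 2))
  expect_true(ci["ror", "lo"] <= fit$ror && fit$ror <= ci["ror", "hi"])
  expect_true(ci["ic", "lo"] <= fit$ic && fit$ic <= ci["ic", "hi"])
  df <- as.data.frame(fit)
  expect_equal(df$n11, 36)
  expect_output(print(fit), "signal detected \\(both ROR and IC\\)")
})
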