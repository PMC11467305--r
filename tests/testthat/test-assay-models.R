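test_that("single-dose fits equal the closed-form solution", {
  # f = -ln(1 - k/n) / d, checked at several (k, n, d)
  cases <- expand.grid(k = c(1, 3, 5, 9), n = 10, d = c(100, 1000, 50000))
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], {
      tab <- data.frame(dose = d, n_tested = n, n_positive = k)
      fit <- fit_single_hit(tab)
      closed <- -log(1 - k / n) / d
      expect_equal(fit$f_hat, closed, tolerance = 1e-10)
    })
  }
})

test_that("frequency estimate is scale-equivariant in dose", {
  tab <- data.frame(dose = c(1e3, 1e4, 1e5), n_tested = 20,
                    n_positive = c(2, 9, 19))
  f1 <- fit_single_hit(tab)$f_hat
  tab2 <- transform(tab, dose = dose * 7)
  expect_equal(fit_single_hit(tab2)$f_hat, f1 / 7, tolerance = 1e-8)
})

test_that("the fitted maximum dominates a log-likelihood grid", {
  tab <- data.frame(dose = c(500, 5000, 50000), n_tested = 12,
                    n_positive = c(1, 6, 11))
  fit <- fit_single_hit(tab)
  grid <- exp(seq(log(fit$f_hat / 10), log(fit$f_hat * 10), length.out = 200))
  lls <- vapply(grid, pedscreen:::loglik_single_hit, numeric(1), table = tab)
  expect_true(all(fit$loglik >= lls - 1e-9))
})

test_that("MLE agrees with the complementary log-log GLM oracle", {
  tab <- data.frame(dose = c(1e3, 1e4, 1e5), n_tested = 20,
                    n_positive = c(3, 12, 20))
  fit <- fit_single_hit(tab)
  g <- stats::glm(cbind(n_positive, n_tested - n_positive) ~ 1 + offset(log(dose)),
                  family = binomial(link = "cloglog"), data = tab)
  expect_equal(fit$f_hat, exp(unname(coef(g))), tolerance = 1e-6)
})

test_that("boundary outcome tables yield flagged one-sided intervals", {
  allneg <- data.frame(dose = c(100, 1000), n_tested = 10, n_positive = 0)
  f0 <- fit_single_hit(allneg)
  expect_equal(f0$f_hat, 0)
  expect_equal(f0$boundary, "all_negative")
  expect_equal(unname(f0$ci95["low"]), 0)
  # closed form upper bound: deviance qchisq(.95,1) at f = crit/(2*sum(n d))
  expect_equal(unname(f0$ci95["high"]),
               qchisq(0.95, 1) / 2 / sum(allneg$n_tested * allneg$dose),
               tolerance = 1e-8)
  allpos <- data.frame(dose = c(100, 1000), n_tested = 10, n_positive = 10)
  finf <- fit_single_hit(allpos)
  expect_equal(finf$f_hat, Inf)
  expect_equal(finf$boundary, "all_positive")
  expect_true(is.finite(finf$ci95["low"]) && finf$ci95["low"] > 0)
})

test_that("likelihood-ratio confidence intervals cover the truth ~95% of the time", {
  f_true <- 1e-4
  hits <- 0L
  for (i in 1:500) {
    tab <- simulate_limiting_dilution(f_true, c(1e3, 1e4, 1e5), 20, seed = i)
    fit <- fit_single_hit(tab)
    if (fit$ci95["low"] <= f_true && f_true <= fit$ci95["high"]) hits <- hits + 1L
  }
  expect_gte(hits / 500, 0.93)
  expect_lte(hits / 500, 0.97)
})

test_that("group comparison is calibrated under the null and powered at 10x", {
  identical_tab <- data.frame(dose = c(1e3, 1e4), n_tested = 10, n_positive = c(2, 7))
  same <- compare_frequencies(identical_tab, identical_tab)
  expect_equal(same$statistic, 0, tolerance = 1e-6)
  expect_equal(same$p_value, 1, tolerance = 1e-4)

  rej_null <- 0L
  for (i in 1:500) {
    a <- simulate_limiting_dilution(1e-4, c(1e3, 1e4, 1e5), 20, seed = 1000 + i)
    b <- simulate_limiting_dilution(1e-4, c(1e3, 1e4, 1e5), 20, seed = 9000 + i)
    if (compare_frequencies(a, b)$p_value < 0.05) rej_null <- rej_null + 1L
  }
  expect_gte(rej_null / 500, 0.03)
  expect_lte(rej_null / 500, 0.07)

  rej_alt <- 0L
  for (i in 1:100) {
    a <- simulate_limiting_dilution(1e-5, c(1e3, 1e4, 1e5), 20, seed = 100 + i)
    b <- simulate_limiting_dilution(1e-4, c(1e3, 1e4, 1e5), 20, seed = 5000 + i)
    if (compare_frequencies(a, b)$p_value < 0.05) rej_alt <- rej_alt + 1L
  }
  expect_gt(rej_alt / 100, 0.5)
})

test_that("median recovered frequency sits near the truth at the default design", {
  f_true <- 1e-4
  f_hats <- vapply(1:100, function(i) {
    fit_single_hit(simulate_limiting_dilution(f_true, c(1e3, 1e4, 1e5), 20,
                                              seed = 300 + i))$f_hat
  }, numeric(1))
  expect_lt(abs(stats::median(f_hats) / f_true - 1), 0.15)
})

test_that("ddCt fold changes follow 2^-ddCt with the control pinned at 1", {
  rec <- data.frame(
    sample = c("v1", "v2", "m1", "m2", "w1"),
    condition = c("vector", "vector", "mutant", "mutant", "wild"),
    target_ct = c(24, 24, 22, 22, 25),
    reference_ct = c(18, 18, 18, 18, 18))
  out <- relative_expression(rec, "vector")
  expect_equal(out$fold[out$condition == "vector"], 1)      # ddCt = 0
  expect_equal(out$fold[out$condition == "mutant"], 4)      # ddCt = -2
  expect_equal(out$fold[out$condition == "wild"], 0.5)      # ddCt = +1
  # technical triplicates are averaged per sample before the condition mean
  tri <- data.frame(sample = rep(c("v1", "m1"), each = 3),
                    condition = rep(c("vector", "mutant"), each = 3),
                    target_ct = c(24.1, 23.9, 24.0, 22.2, 21.8, 22.0),
                    reference_ct = 18)
  out2 <- relative_expression(tri, "vector")
  expect_equal(out2$fold[out2$condition == "mutant"], 2^2, tolerance = 1e-9)
  expect_error(relative_expression(rec, "absent"), "control")
})

test_that("tumor volume follows the (length x width^2)/2 formula", {
  expect_equal(tumor_volume(10, 6), 180)
  expect_equal(tumor_volume(7, 0), 0)
  expect_equal(tumor_volume(5, 5), 62.5)
  expect_equal(tumor_volume(c(10, 5), c(6, 5)), c(180, 62.5))
  expect_warning(tumor_volume(4, 6), "width exceeds")
  expect_error(tumor_volume(-1, 2), "non-negative")
})
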