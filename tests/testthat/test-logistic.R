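test_that("IRLS matches the reference GLM fit on simulated data", {
  set.seed(14)
  x <- rnorm(300, 0, 1.5)
  y <- runif(300) < plogis(0.4 - 1.1 * x)
  ours <- fit_logistic(x, y)
  ref <- stats::glm(y ~ x, family = stats::binomial())
  expect_equal(ours$beta0, unname(coef(ref)[1]), tolerance = 1e-6)
  expect_equal(ours$beta1, unname(coef(ref)[2]), tolerance = 1e-6)
  se_ref <- sqrt(diag(vcov(ref)))
  expect_equal(ours$se_beta1, unname(se_ref[2]), tolerance = 1e-3)
  expect_equal(ours$p_value,
               summary(ref)$coefficients[2, 4], tolerance = 1e-3)
  expect_true(ours$converged)
  expect_lte(ours$n_iter, 100)
})

test_that("a symmetric design gives the null fit, degenerate inputs error", {
  fit <- fit_logistic(c(0, 0, 1, 1), c(0, 1, 0, 1))
  expect_equal(fit$beta0, 0)
  expect_equal(fit$beta1, 0)
  expect_error(fit_logistic(1:4, c(1, 1, 1, 1)), "both outcome classes")
  expect_error(fit_logistic(c(1, 2, 3, 4), c(1, 1, 0, 0)),
               "perfect separation")
})

test_that("parameter recovery from the published WTR link at n = 5000", {
  set.seed(14)
  x <- rlnorm(5000, log(0.008), log(1.8)) # WTR-scale predictor
  y <- runif(5000) < plogis(0.577 - 72.8 * x)
  fit <- fit_logistic(x, y, "WTR")
  expect_lt(abs(fit$beta0 - 0.577) / fit$se_beta0, 2)
  expect_lt(abs(fit$beta1 - (-72.8)) / fit$se_beta1, 2)
})

test_that("critical value inverts the model and reproduces printed figures", {
  m_all <- logistic_model(0.577, -72.8, "WTR")
  m_cor <- logistic_model(0.298, -48.3, "WTR_prime")
  expect_equal(critical_value(m_all), 0.577 / 72.8)
  expect_equal(signif(critical_value(m_all), 2), 7.9e-3)
  expect_equal(signif(critical_value(m_cor), 2), 6.2e-3)
  expect_equal(critical_value(logistic_model(0, -5)), 0)
  # general p: logit(p) shift
  expect_equal(critical_value(m_all, 0.75),
               (qlogis(0.75) - 0.577) / -72.8)
  expect_error(critical_value(logistic_model(1, 0)), "no crossing")
})

test_that("fitted probability at the critical value is one half", {
  set.seed(9)
  rec <- random_records(120)
  wtr <- compute_indices(rec)$WTR
  y <- runif(120) < plogis(0.577 - 72.8 * wtr)
  y[1:2] <- c(TRUE, FALSE)
  fit <- fit_logistic(wtr, y, "WTR")
  expect_equal(predict(fit, critical_value(fit)), 0.5, tolerance = 1e-9)
})

test_that("odds ratios per increment use the magnitude convention", {
  expect_equal(round(odds_ratio_per_delta(logistic_model(0.577, -72.8),
                                          0.001), 2), 1.08)
  expect_equal(round(odds_ratio_per_delta(logistic_model(0.298, -48.3),
                                          0.001), 2), 1.05)
  expect_equal(odds_ratio_per_delta(logistic_model(1, 0), 0.001), 1.0)
  expect_gte(odds_ratio_per_delta(logistic_model(0, 3), 0.5), 1)
})

test_that("percent difference uses the cohort-calculated denominator", {
  expect_equal(round(percent_difference(6.1e-3, 0.577 / 72.8)), 23)
  expect_equal(percent_difference(5, 5), 0)
  expect_equal(percent_difference(0, 4), 100)
  expect_error(percent_difference(1, 0), "nonzero")
})

test_that("Welch t-test reports the hand-computed statistic and df", {
  out <- welch_t_test(c(1, 2, 3), c(4, 5, 6), variable = "h")
  expect_equal(out$statistic, -3 / sqrt(2 / 3)) # hand Welch formula
  expect_equal(round(out$statistic, 3), -3.674)
  expect_equal(out$df, 4)
  expect_equal(out$test, "welch_t")
  # swapping the samples negates t, p unchanged
  swap <- welch_t_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swap$statistic, -out$statistic)
  expect_equal(swap$p_value, out$p_value)
  # identical samples: t = 0, p = 1
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(welch_t_test(c(1, 1), c(1, 1)), "degenerate")
  expect_error(welch_t_test(1, c(1, 2)), "two observations")
})

test_that("chi-squared test is Pearson without continuity correction", {
  out <- chi_squared_test(matrix(c(20, 10, 10, 20), 2), variable = "site")
  expect_equal(out$statistic, 20 / 3, tolerance = 1e-10)
  expect_equal(out$df, 1)
  # proportional rows: statistic 0, p = 1
  flat <- chi_squared_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(chi_squared_test(matrix(c(0, 0, 5, 5), 2)), "expected")
})
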