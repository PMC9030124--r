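test_that("groups are partitioned with counts and small groups flagged", {
  set.seed(5)
  rec <- rbind(sim_records(30, 0, 1, seed = NULL),
               transform(sim_records(5, 0, 1, seed = NULL),
                         group = "volatile"))
  g <- assemble_groups(rec, min_n = 20)
  expect_setequal(names(g$datasets), "powders_granules")
  expect_identical(g$excluded, "volatile")
  expect_identical(g$summary$n[g$summary$group == "powders_granules"], 30L)

  g2 <- assemble_groups(rec, min_n = 20, force = TRUE)
  expect_setequal(names(g2$datasets), c("powders_granules", "volatile"))

  empty <- assemble_groups(rec[0, ], min_n = 20)
  expect_length(empty$datasets, 0)
})

test_that("noiseless data recover the generating line exactly", {
  d <- sim_records(60, alpha = 0.5, beta = 1, sigma_bc = 0, sigma_res = 0,
                   seed = 101)
  fit <- suppressWarnings(fit_calibration(d, mode = "sm"))
  expect_equal(fit$alpha, 0.5, tolerance = 1e-6)
  expect_equal(fit$beta, 1, tolerance = 1e-6)
  expect_lt(sum(fit$varcomp), 1e-8)
})

test_that("mixed fit reduces to OLS when random effects are absent", {
  d <- sim_records(80, alpha = 1, beta = 0.8, sigma_bc = 0,
                   sigma_res = 0.4, seed = 7)
  fit <- suppressWarnings(fit_calibration(d, mode = "sm"))
  ols <- lm(log(concentration) ~ log(score), data = d)
  expect_equal(fit$alpha, unname(coef(ols)[1]), tolerance = 0.02)
  expect_equal(fit$beta, unname(coef(ols)[2]), tolerance = 0.02)
})

test_that("art mode returns three variance components", {
  set.seed(9)
  d <- sim_records(120, alpha = 0, beta = 1, sigma_bc = 0.4,
                   sigma_res = 0.3, n_companies = 8)
  d$worker <- paste0(d$company, "_w", rep_len(1:3, nrow(d)))
  fit <- suppressWarnings(fit_calibration(d, mode = "art"))
  expect_named(fit$varcomp, c("between_company", "between_worker",
                              "within_worker"))
  expect_true(all(fit$varcomp >= 0))
})

test_that("one-company data report zero between-company variance with a warning", {
  d <- sim_records(40, alpha = 0, beta = 1, sigma_res = 0.3,
                   n_companies = 1, seed = 3)
  expect_warning(fit <- fit_calibration(d, mode = "sm"), "one company")
  expect_identical(unname(fit$varcomp["between_company"]), 0)
})

test_that("records below the minimum, or non-positive, are rejected", {
  d <- sim_records(3, 0, 1, seed = 2)
  expect_error(fit_calibration(d), "minimum")
  d2 <- sim_records(30, 0, 1, seed = 2)
  d2$concentration[1] <- 0
  expect_error(fit_calibration(d2), "positive")
})

test_that("fixed-slope mode pins the slope at one", {
  d <- sim_records(60, alpha = log(2), beta = 0.7, sigma_res = 0.3,
                   seed = 12)
  fit <- suppressWarnings(fit_calibration(d, fix_slope = TRUE))
  expect_identical(fit$beta, 1)
})

test_that("predict_gm is exp(alpha + beta ln score)", {
  f <- calibration_fit(alpha = 0, beta = 1)
  expect_equal(predict_gm(f, 7), 7)
  f2 <- calibration_fit(alpha = log(2), beta = 1)
  expect_equal(predict_gm(f2, 3), 6)
  expect_error(predict_gm(f, 0), "positive")
})

test_that("percentile prediction follows the lognormal quantile formula", {
  # GSD 2: the 84.13th percentile sits one GSD above the GM
  f <- calibration_fit(alpha = 0, beta = 1,
                       varcomp = c(between_company = log(2)^2 / 2,
                                   within_company = log(2)^2 / 2))
  expect_equal(predict_percentile(f, 5, 0.8413), 10, tolerance = 1e-3)
  expect_equal(predict_percentile(f, 5, 0.5), predict_gm(f, 5))
  expect_error(predict_percentile(f, 5, 1.2), "between 0 and 1")
})

test_that("percentile prediction is monotone in p and in score", {
  f <- calibration_fit(alpha = 0.3, beta = 0.8,
                       varcomp = c(between_company = 0.2,
                                   within_company = 0.3))
  ps <- c(0.1, 0.5, 0.9, 0.95)
  vals <- vapply(ps, function(p) predict_percentile(f, 4, p), numeric(1))
  expect_true(all(diff(vals) > 0))
  scores <- c(0.5, 2, 8, 32)
  vals2 <- vapply(scores, function(s) predict_percentile(f, s, 0.9),
                  numeric(1))
  expect_true(all(diff(vals2) > 0))
})

test_that("bootstrap upper bound dominates the point percentile and is reproducible", {
  d <- sim_records(100, alpha = 1, beta = 0.8, sigma_bc = 0.3,
                   sigma_res = 0.4, n_companies = 10, seed = 21)
  fit <- suppressWarnings(fit_calibration(d))
  pt <- predict_percentile(fit, 10, 0.9)
  ub1 <- predict_percentile(fit, 10, 0.9, conf = 0.95, seed = 99)
  ub2 <- predict_percentile(fit, 10, 0.9, conf = 0.95, seed = 99)
  expect_gte(ub1, pt)
  expect_identical(ub1, ub2)
})

test_that("estimator bias shrinks as the sample grows", {
  err <- vapply(c(100, 1000), function(n) {
    est <- vapply(1:10, function(r) {
      d <- sim_records(n, alpha = 1, beta = 0.8, sigma_bc = 0.3,
                       sigma_res = 0.4, n_companies = 10,
                       seed = 1000 + r * 17 + n)
      fit <- suppressWarnings(fit_calibration(d))
      c(fit$alpha, fit$beta)
    }, numeric(2))
    abs(rowMeans(est) - c(1, 0.8))
  }, numeric(2))
  expect_true(all(err[, 2] < err[, 1] + 0.05))
  expect_lt(max(err[, 2]), 0.05)
})

test_that("pooling heterogeneous strata inflates residual variance", {
  # two sub-populations with different intercepts pooled into one "group"
  d1 <- sim_records(80, alpha = 0, beta = 1, sigma_res = 0.2, seed = 41)
  d2 <- sim_records(80, alpha = 2, beta = 1, sigma_res = 0.2, seed = 42)
  pooled <- rbind(d1, d2)
  pooled$company <- rep_len(sprintf("c%02d", 1:5), nrow(pooled))
  f1 <- suppressWarnings(fit_calibration(d1))
  f2 <- suppressWarnings(fit_calibration(d2))
  fp <- suppressWarnings(fit_calibration(pooled))
  expect_gt(sum(fp$varcomp), max(sum(f1$varcomp), sum(f2$varcomp)))

  # stratum-specific prediction error increases under the pooled line
  err_strat <- mean((log(predict_gm(f1, d1$score)) -
                       log(d1$concentration))^2)
  err_pool <- mean((log(predict_gm(fp, d1$score)) -
                      log(d1$concentration))^2)
  expect_gt(err_pool, err_strat)
})
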