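test_that("ratio statistics summarize predicted/measured spread", {
  cs <- comparison_set(c(1, 2, 3), c(1, 2, 3))
  rs <- ratio_stats(cs)
  expect_equal(rs$gm_ratio, 1)
  expect_equal(rs$ratio_range, 1)
  expect_equal(rs$within_factor2, 1)

  cs2 <- comparison_set(c(0.1, 10), c(1, 1))
  expect_equal(ratio_stats(cs2)$ratio_range, 100)
  expect_equal(ratio_stats(cs2)$gm_ratio, 1)
  expect_equal(ratio_stats(cs2)$within_factor2, 0)
  expect_equal(ratio_stats(cs2)$within_factor10, 1)

  expect_equal(ratio_stats(comparison_set(5, 1))$ratio_range, 1)
  expect_error(comparison_set(numeric(), numeric()), "length")
  expect_error(comparison_set(c(1, -1), c(1, 1)), "positive")
})

test_that("correlations match direct formulas, Spearman uses midranks", {
  up <- comparison_set(c(1, 2, 5, 9), c(2, 3, 8, 20))
  cc <- correlation_summary(up)
  expect_equal(cc$spearman, 1)
  down <- comparison_set(c(9, 5, 2, 1), c(2, 3, 8, 20))
  expect_equal(correlation_summary(down)$spearman, -1)

  mixed <- comparison_set(c(1, 2, 3), c(2, 1, 3))
  expect_equal(correlation_summary(mixed)$spearman, 0.5)

  flat <- comparison_set(c(1, 1, 1), c(1, 2, 3))
  expect_true(correlation_summary(flat)$degenerate)
  expect_error(correlation_summary(comparison_set(c(1, 2), c(1, 2))),
               "at least 3")
})

test_that("Spearman equals the brute-force rank oracle on all permutations of n <= 5", {
  for (n in 3:5) {
    y <- seq_len(n)
    perms <- .permutations(n)
    for (i in seq_len(nrow(perms))) {
      x <- as.numeric(perms[i, ])
      cs <- comparison_set(exp(x), exp(y))  # ln-scale recovers x, y
      expect_equal(correlation_summary(cs)$spearman, oracle_spearman(x, y))
    }
  }
})

test_that("residual trend flags attenuation but not pure bias", {
  set.seed(19)
  measured <- exp(runif(40, log(0.1), log(100)))
  ident <- comparison_set(measured, measured)
  rt0 <- residual_trend(ident)
  expect_equal(rt0$slope, 0)
  expect_false(rt0$flag)

  atten <- comparison_set(measured^0.5, measured)
  rt1 <- residual_trend(atten)
  expect_equal(rt1$slope, -0.5, tolerance = 1e-9)
  expect_true(rt1$flag)

  biased <- comparison_set(2 * measured, measured)
  rt2 <- residual_trend(biased)
  expect_equal(rt2$slope, 0, tolerance = 1e-9)
  expect_false(rt2$flag)
})

test_that("exceedance fraction counts measurements above the estimate", {
  m <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  expect_equal(exceedance_fraction(comparison_set(rep(100, 10), m)), 0)
  expect_equal(exceedance_fraction(comparison_set(rep(5.5, 10), m)), 0.5)
  expect_equal(exceedance_fraction(comparison_set(rep(0.5, 10), m)), 1)
  # invariant under a monotone rescaling of both channels
  cs <- comparison_set(rep(5.5, 10), m)
  cs2 <- comparison_set(rep(5.5, 10)^3, m^3)
  expect_equal(exceedance_fraction(cs), exceedance_fraction(cs2))
})

test_that("SEC verdict is exactly the conjunction of its three criteria", {
  # construct a case for every combination of (n, correlation, exceedance)
  make_case <- function(n_ok, r_ok, ex_ok) {
    n <- if (n_ok) 25 else 19
    measured <- exp(seq(0, 3, length.out = n))
    predicted <- if (r_ok) measured * 1.01 else
      rev(measured) + max(measured)  # anti-monotone yet above all measured
    if (!ex_ok) predicted <- measured * 0.5  # all measurements exceed
    comparison_set(predicted, measured)
  }
  for (n_ok in c(TRUE, FALSE)) for (r_ok in c(TRUE, FALSE))
    for (ex_ok in c(TRUE, FALSE)) {
      if (!ex_ok && !r_ok) next  # exceedance case fixes r = 1
      res <- sec_criteria_check(make_case(n_ok, r_ok, ex_ok))
      expect_identical(unname(res$criteria["n_ge_20"]), n_ok)
      expect_identical(unname(res$criteria["spearman_ge_0.6"]), r_ok)
      expect_identical(unname(res$criteria["exceedance_le_0.10"]), ex_ok)
      expect_identical(res$overall_pass, n_ok && r_ok && ex_ok)
      expect_identical(res$overall_pass, all(res$criteria))
    }
})

test_that("SEC thresholds sit exactly at n=20, r=0.6, 10%", {
  measured <- exp(seq(0, 3, length.out = 20))
  pass <- sec_criteria_check(comparison_set(measured * 1.01, measured))
  expect_true(pass$overall_pass)

  n19 <- sec_criteria_check(comparison_set(measured[-1] * 1.01,
                                           measured[-1]))
  expect_false(unname(n19$criteria["n_ge_20"]))
  expect_false(n19$overall_pass)

  # exactly 10% exceedance passes; more fails
  m <- exp(seq(0, 3, length.out = 20))
  p <- m * 1.01
  p[1:2] <- m[1:2] * 0.99
  ex10 <- sec_criteria_check(comparison_set(p, m))
  expect_equal(ex10$exceedance_fraction, 0.10)
  expect_true(unname(ex10$criteria["exceedance_le_0.10"]))
  p[3] <- m[3] * 0.99
  ex15 <- sec_criteria_check(comparison_set(p, m))
  expect_false(unname(ex15$criteria["exceedance_le_0.10"]))
})

test_that("tier inversions and underestimation are both flagged", {
  ok <- tier_conservatism_check(c(tier1 = 10, tier2 = 5))
  expect_true(ok$pass)
  expect_identical(nrow(ok$inversions), 0L)

  inv <- tier_conservatism_check(c(tier1 = 5, tier2 = 10))
  expect_false(inv$pass)
  expect_identical(inv$inversions$higher_tier, "tier2")

  both <- tier_conservatism_check(c(tier1 = 5, tier2 = 10), measured = 7)
  expect_false(both$pass)
  expect_identical(both$underestimating_tiers, "tier1")
  expect_identical(nrow(both$inversions), 1L)

  expect_error(tier_conservatism_check(c(tier1 = 5)), "two tiers")
})

test_that("a log-symmetric ratio range converts to the implied interval", {
  expect_equal(accuracy_interval(1, 100), c(lower = 0.1, upper = 10))
  expect_equal(accuracy_interval(1, 10),
               c(lower = 1 / sqrt(10), upper = sqrt(10)))
  expect_equal(accuracy_interval(5, 1), c(lower = 5, upper = 5))
})

test_that("the closed loop reproduces weak validation performance under noise", {
  cfg <- study_config(group_counts = c(powders_granules = 150),
                      companies_per_group = 10, p_mis = 0.3, seed = 88)
  st <- make_study(cfg)
  fit <- suppressWarnings(fit_calibration(as.data.frame(st), mode = "sm"))
  sigma_tot <- sqrt(sum(fit$varcomp))
  pred <- predict_gm(fit, st$score) * exp(qnorm(0.9) * sigma_tot)
  cs <- comparison_set(pred, st$concentration, flavour = "percentile")
  rt <- residual_trend(cs)
  expect_true(rt$flag)
  expect_lt(fit$beta, 1)
})
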