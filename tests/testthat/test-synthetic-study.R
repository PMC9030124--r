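test_that("study generation is deterministic under a fixed seed", {
  cfg <- study_config(group_counts = c(powders_granules = 60),
                      companies_per_group = 6, seed = 33)
  s1 <- make_study(cfg)
  s2 <- make_study(cfg)
  expect_identical(s1, s2)
  s3 <- make_study(study_config(group_counts = c(powders_granules = 60),
                                companies_per_group = 6, seed = 34))
  expect_false(identical(s1$concentration, s3$concentration))
})

test_that("the default configuration reproduces the pooled study structure", {
  st <- make_study(study_config(seed = 2))
  expect_identical(nrow(st), 952L)
  counts <- table(st$group)
  expect_identical(as.integer(counts[c("powders_granules", "comminuting",
                                       "low_volatile", "volatile")]),
                   c(408L, 112L, 256L, 176L))
  expect_identical(length(unique(st$company)), 4L * 12L)
})

test_that("a degenerate noiseless stratum lands on the mechanistic value", {
  # single stratum, single-choice scenario grid, no noise of any kind:
  # every concentration equals the stratum's anchored steady-state value
  box <- two_compartment_params(V_nf = 8, V_ff = 100, Q = 5, beta = 5,
                                G = 100)
  cfg <- study_config(group_counts = c(powders_granules = 24),
                      companies_per_group = 3, n_strata = 1,
                      strata = list(list(beta = 1, E_shift = 1,
                                         box = box)),
                      sigma_bc = 0, sigma_bw = 0, measurement_gsd = 1,
                      p_mis = 0, seed = 4)
  st <- make_study(cfg)
  M <- unname(steady_state(box)["C_nf"])
  # concentrations sit on the stratum line through the mechanistic anchor
  expect_equal(st$concentration, st$gm_true, tolerance = 1e-12)
  expect_true(all(st$concentration > 0))
  # the anchor itself: a record at the reference score hits M exactly
  alpha <- log(M) - log(exposcore:::.sm_score_from_values(
    exposcore:::.reference_values(exposcore:::.stratum_factors(
      cfg$strata[[1]]))))
  expect_equal(unique(round(log(st$gm_true) - log(st$score_true), 10)),
               round(alpha, 10))
})

test_that("assessor noise perturbs only qualitative multipliers, one grid step", {
  v <- c(E = 1, H = 3, t_h = 0.3)
  qual <- c(TRUE, TRUE, FALSE)
  expect_identical(emulate_assessor(v, qual, p_mis = 0, seed = 1), v)

  out <- emulate_assessor(v, qual, p_mis = 1, seed = 5)
  expect_identical(unname(out["t_h"]), 0.3)  # quantitative: never moved
  expect_true(out["E"] %in% c(0.3, 3))
  expect_true(out["H"] %in% c(1, 10))

  set.seed(8)
  draws <- replicate(10000, emulate_assessor(c(x = 1), TRUE, p_mis = 1)["x"])
  expect_setequal(unique(draws), c(0.3, 3))
  # direction is a fair coin: binomial check at n = 10^4
  expect_lt(abs(mean(draws == 3) - 0.5), 0.02)

  expect_error(emulate_assessor(c(x = 2.5), TRUE, p_mis = 1), "grid")
})

test_that("assigned multipliers stay on the taxonomy grid", {
  st <- make_study(study_config(group_counts = c(powders_granules = 80),
                                seed = 6))
  qual <- c("E", "H", "eta_lcnf", "eta_gvnf", "eta_lcff", "eta_gvff", "a")
  for (nm in qual) {
    expect_true(all(on_grid(st[[paste0(nm, "_obs")]])))
    expect_true(all(on_grid(st[[paste0(nm, "_true")]])))
  }
})

test_that("a noiseless closed loop recovers the generating slope", {
  cfg <- study_config(group_counts = c(powders_granules = 200),
                      companies_per_group = 20, n_strata = 1,
                      alpha = 1, beta = 1, sigma_bc = 0, sigma_bw = 0,
                      measurement_gsd = 1, p_mis = 0, seed = 10)
  st <- make_study(cfg)
  expect_equal(st$score, st$score_true)
  fit <- suppressWarnings(
    fit_calibration(as.data.frame(st), mode = "sm"))
  expect_equal(fit$beta, 1, tolerance = 1e-6)
  expect_equal(fit$alpha, 1, tolerance = 1e-6)
})

test_that("assignment noise attenuates the fitted slope, monotonically in p_mis", {
  slope_at <- function(p_mis, seed) {
    cfg <- study_config(group_counts = c(powders_granules = 300),
                        companies_per_group = 10, n_strata = 1,
                        alpha = 1, beta = 1, sigma_bc = 0.2,
                        sigma_bw = 0, measurement_gsd = 1.3,
                        p_mis = p_mis, seed = seed)
    st <- make_study(cfg)
    suppressWarnings(fit_calibration(as.data.frame(st), mode = "sm"))$beta
  }
  # average over a few seeds to damp replicate noise
  seeds <- c(101, 202, 303)
  slopes <- vapply(c(0, 0.1, 0.3, 0.5), function(p) {
    mean(vapply(seeds, function(s) slope_at(p, s), numeric(1)))
  }, numeric(1))
  expect_equal(slopes[1], 1, tolerance = 0.05)
  expect_true(all(diff(slopes) < 0))
  expect_lt(slopes[3], 1)
})

test_that("pooling strata with different intercepts inflates residual variance", {
  base <- list(group_counts = c(powders_granules = 240),
               companies_per_group = 12, sigma_bc = 0, sigma_bw = 0,
               measurement_gsd = 1.2, p_mis = 0, seed = 77)
  box_lo <- two_compartment_params(V_nf = 8, V_ff = 100, Q = 20,
                                   beta = 10, G = 20)
  box_hi <- two_compartment_params(V_nf = 8, V_ff = 100, Q = 2,
                                   beta = 2, G = 300)
  one <- function(strata) {
    cfg <- do.call(study_config, c(base, list(strata = strata)))
    st <- make_study(cfg)
    suppressWarnings(fit_calibration(as.data.frame(st), mode = "sm"))
  }
  f_lo <- one(list(list(beta = 1, E_shift = 1, box = box_lo)))
  f_hi <- one(list(list(beta = 1, E_shift = 1, box = box_hi)))
  f_pool <- one(list(list(beta = 1, E_shift = 1, box = box_lo),
                     list(beta = 1, E_shift = 1, box = box_hi)))
  expect_gt(sum(f_pool$varcomp),
            max(sum(f_lo$varcomp), sum(f_hi$varcomp)))
})

test_that("study export round-trips the observed channel", {
  cfg <- study_config(group_counts = c(powders_granules = 40),
                      companies_per_group = 4, seed = 55)
  st <- make_study(cfg)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  export_study(st, csv, js)
  back <- read.csv(csv)
  expect_identical(nrow(back), 40L)
  expect_equal(back$concentration_mg_m3, st$concentration)
  expect_equal(back$score, st$score)
  expect_identical(unique(back$seed), 55L)
  truth <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_identical(truth$seed, 55L)
  expect_identical(nrow(truth$records), 40L)
})
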