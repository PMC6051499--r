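test_that("calibration cohort has the forced structure", {
  cohort <- gen_calibration_cohort(cohort_params(n_yc = 18, n_ad = 18,
                                                 seed = 11))
  expect_equal(nrow(cohort), 36)
  expect_equal(unname(table(cohort$group)[c("YC", "AD")]), c(18L, 18L),
               ignore_attr = TRUE)

  # noiseless affine relation is exact
  p <- cohort_params(method_noise_sd = 0, method_slope = 2,
                     method_intercept = -1, seed = 5)
  c0 <- gen_calibration_cohort(p)
  expect_equal(c0$method_value, 2 * c0$standard_suvr - 1)
})

test_that("calibration cohort parameter validation names the field", {
  expect_error(cohort_params(n_yc = 1), "n_yc")
  expect_error(cohort_params(yc_sd = -0.1), "yc_sd")
  expect_error(cohort_params(yc_mean_std_suvr = 2, ad_mean_std_suvr = 1.5),
               "ad_mean_std_suvr")
})

test_that("fixed seeds reproduce generated tables bit-identically", {
  p <- cohort_params(seed = 99)
  expect_identical(gen_calibration_cohort(p), gen_calibration_cohort(p))
  lp <- longitudinal_sim_params(seed = 99)
  expect_identical(gen_longitudinal_cohort(lp), gen_longitudinal_cohort(lp))
  expect_identical(
    gen_cross_sectional_cohort(n = 50, seed = 3),
    gen_cross_sectional_cohort(n = 50, seed = 3))
  # generation does not perturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(gen_calibration_cohort(p)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("large calibration cohorts recover the generating moments", {
  p <- cohort_params(n_yc = 10000, n_ad = 10000, yc_mean_std_suvr = 1.1,
                     yc_sd = 0.05, method_slope = 2, method_intercept = -1,
                     method_noise_sd = 0.05, seed = 17)
  cohort <- gen_calibration_cohort(p)
  yc <- cohort[cohort$group == "YC", ]
  se <- 0.05 / sqrt(10000)
  expect_lt(abs(mean(yc$standard_suvr) - 1.1), 3 * se)
  # OLS of standard on method recovers the inverse slope 1/2
  fit <- lm(standard_suvr ~ method_value, data = cohort)
  slope_hat <- unname(coef(fit)[2])
  se_slope <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(slope_hat - 0.5), 3 * se_slope + 1e-3)
})

test_that("longitudinal truth follows the rate function exactly", {
  # zero-rate, zero-noise: follow-up equals baseline
  lp0 <- longitudinal_sim_params(n_subjects = 40,
                                 rate_function = rate_function("constant", 0),
                                 measurement_noise_sd = 0, seed = 2)
  lc0 <- gen_longitudinal_cohort(lp0)
  expect_equal(lc0$followup_cl, lc0$baseline_cl)

  # machine-precision Euler identity for a general cohort
  lp <- longitudinal_sim_params(seed = 4)
  lc <- gen_longitudinal_cohort(lp)
  expect_equal(lc$followup_true - lc$baseline_true,
               eval_rate(lp$rate_function, lc$baseline_true) * lc$interval,
               tolerance = 1e-12)

  # forced arithmetic: rate 1.5 CL/yr at baseline 30, 2-yr interval
  rf <- rate_function("piecewise_linear", c(0.15, -0.5),
                      true_zero_crossing = 20)
  expect_equal(eval_rate(rf, 30), 1.5)
  expect_equal(30 + eval_rate(rf, 30) * 2, 33)
})

test_that("intervals are truncated-normal with the right mean", {
  lp <- longitudinal_sim_params(n_subjects = 243, interval_mean = 3.2,
                                interval_sd = 1.5, seed = 21)
  lc <- gen_longitudinal_cohort(lp)
  expect_true(all(lc$interval > 0.5))
  # oracle: mean of a normal truncated below at a = (0.5 - 3.2)/1.5
  a <- (0.5 - 3.2) / 1.5
  truth <- 3.2 + 1.5 * dnorm(a) / (1 - pnorm(a))
  expect_lt(abs(mean(lc$interval) - truth), 3 * 1.5 / sqrt(243))
})

test_that("rate_function families expose their zero crossing", {
  rf <- rate_function("quadratic_dip", c(0.02, 5, -0.5))
  expect_equal(rf$true_zero_crossing, 5 + sqrt(0.5 / 0.02))
  expect_lt(eval_rate(rf, rf$true_zero_crossing - 1), 0)
  expect_gt(eval_rate(rf, rf$true_zero_crossing + 1), 0)
  rl <- rate_function("logistic", c(-0.5, 5, 0.15, 25))
  expect_equal(eval_rate(rl, rl$true_zero_crossing), 0, tolerance = 1e-10)
  expect_error(rate_function("piecewise_linear", c(0.1, -0.5)),
               "true_zero_crossing")
})

test_that("SRTM generator matches independent oracles", {
  # no binding, unit delivery: target equals reference exactly
  p0 <- srtm_params(R1 = 1, bp_true = 0)
  tt0 <- gen_srtm_tacs(p0)
  expect_equal(tt0$target$activity, tt0$reference$activity, tolerance = 1e-12)

  # RK4 oracle on the model ODE, biexponential reference
  p <- srtm_params(bp_true = 0.5)
  tt <- gen_srtm_tacs(p)
  cr <- biexp_cr(10, 0.005, 0.35)
  oracle <- srtm_rk4(0.9, 0.2, 0.5, p$frame_mid_times, cr$cr, cr$dcr)
  expect_equal(tt$target$activity, oracle, tolerance = 1e-3)

  # closed form for a single-exponential reference
  pse <- srtm_params(R1 = 0.8, k2 = 0.2, bp_true = 1,
                     reference_input = function(t) 10 * exp(-0.01 * t))
  ttse <- gen_srtm_tacs(pse)
  expect_equal(ttse$target$activity,
               srtm_closed_single_exp(0.8, 0.2, 1, 10, 0.01,
                                      pse$frame_mid_times),
               tolerance = 1e-4)

  # late-time ratio approaches DVR within 5% after 60 min
  late <- tt$target$frame_mid_times > 60
  ratio <- tt$target$activity[late] / tt$reference$activity[late]
  expect_true(all(abs(ratio - 1.5) / 1.5 < 0.05))

  # constant reference: asymptote is (1 + BP) * reference, R1-free
  pc <- srtm_params(R1 = 0.7, bp_true = 0.5,
                    frame_mid_times = seq(5, 300, 5),
                    frame_durations = rep(5, 60),
                    reference_input = list(type = "constant", value = 4))
  ttc <- gen_srtm_tacs(pc)
  expect_equal(tail(ttc$target$activity, 1) / 4, 1.5, tolerance = 1e-3)

  expect_error(srtm_params(frame_mid_times = c(10, 5)), "increasing")
})

test_that("mixing phantoms follow the forward model", {
  M <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE)
  expect_equal(gen_pvc_phantom(phantom_spec(c(4, 1), M)), c(3.4, 1.9))
  expect_equal(gen_pvc_phantom(phantom_spec(c(4, 1), diag(2))), c(4, 1))
  # convexity: noiseless observations lie inside the range of the truth
  set.seed(8)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    W <- matrix(runif(k * k), k)
    W <- W / rowSums(W)
    tm <- runif(k, 0, 10)
    obs <- gen_pvc_phantom(phantom_spec(tm, W))
    expect_true(all(obs >= min(tm) - 1e-12 & obs <= max(tm) + 1e-12))
  }
  bad <- matrix(c(0.8, 0.3, 0.3, 0.7), 2, byrow = TRUE)
  expect_error(phantom_spec(c(1, 1), bad), "sum to 1")
  expect_error(phantom_spec(c(-1, 1), diag(2)), "nonnegative")
})

test_that("write_cohort produces a CSV plus JSON sidecar", {
  p <- cohort_params(seed = 6)
  cohort <- gen_calibration_cohort(p)
  path <- file.path(tempdir(), "cal.csv")
  write_cohort(cohort, path, p)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$standard_suvr, cohort$standard_suvr, tolerance = 1e-10)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$seed, 6)
  expect_equal(side$method_slope, p$method_slope)
  unlink(c(path, paste0(path, ".json")))
})
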