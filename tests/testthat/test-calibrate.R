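test_that("standard_cl is exact at the anchors and affine between them", {
  a <- anchor_set(1.05, 2.05)
  expect_identical(standard_cl(1.05, a), 0)
  expect_identical(standard_cl(2.05, a), 100)
  expect_equal(standard_cl((1.05 + 2.05) / 2, a), 50)
  # strictly increasing
  v <- seq(0.8, 2.5, by = 0.05)
  expect_true(all(diff(standard_cl(v, a)) > 0))
  expect_error(anchor_set(2, 1), "exceed")
})

test_that("fit_anchors takes group means and enforces ordering", {
  a <- fit_anchors(c(1.0, 1.2), c(2.0, 2.2))
  expect_equal(a$mu_yc, 1.1)
  expect_equal(a$mu_ad, 2.1)
  expect_error(fit_anchors(c(1, 1.2), c(1, 1.2)), "exceed")
  expect_error(fit_anchors(1, c(2, 2.2)), "at least 2")
  # sampling consistency at n = 10,000 per group
  cohort <- gen_calibration_cohort(cohort_params(
    n_yc = 10000, n_ad = 10000, yc_sd = 0.05, ad_sd = 0.2, seed = 31))
  af <- fit_anchors(cohort$standard_suvr[cohort$group == "YC"],
                    cohort$standard_suvr[cohort$group == "AD"])
  expect_lt(abs(af$mu_yc - 1.05), 3 * 0.05 / sqrt(10000))
  expect_lt(abs(af$mu_ad - 2.05), 3 * 0.20 / sqrt(10000))
})

test_that("level-2 calibration inverts affine methods exactly", {
  anchors <- anchor_set(1.05, 2.05)
  base <- gen_calibration_cohort(cohort_params(method_noise_sd = 0,
                                               seed = 7))
  # identity method: composed equation equals the anchor transform
  eq_id <- fit_level2(base, anchors, "identity")
  expect_equal(eq_id$slope, 100 / (2.05 - 1.05), tolerance = 1e-9)
  expect_equal(eq_id$intercept, -100 * 1.05 / (2.05 - 1.05),
               tolerance = 1e-8)
  expect_equal(eq_id$r_squared, 1, tolerance = 1e-12)
  # noiseless affine method v = 2 s + 1: conversion undoes the relation
  aff <- base
  aff$method_value <- 2 * base$standard_suvr + 1
  eq <- fit_level2(aff, anchors, "affine")
  expect_equal(apply_equation(eq, 2 * base$standard_suvr + 1),
               standard_cl(base$standard_suvr, anchors), tolerance = 1e-9)
  expect_error(fit_level2(transform(base, method_value = 1), anchors),
               "constant")
  expect_error(fit_level2(base[1:3, ], anchors), "n >= 4")
})

test_that("level-2 slope recovery is accurate over repeated noisy cohorts", {
  anchors <- anchor_set(1.05, 2.05)
  true_slope <- 100 * (1 / 2) / (2.05 - 1.05)  # inverse of method slope 2
  rel_err <- sapply(1:100, function(s) {
    cohort <- gen_calibration_cohort(cohort_params(
      method_slope = 2, method_intercept = -1, method_noise_sd = 0.05,
      seed = s))
    eq <- fit_level2(cohort, anchors, "m")
    abs(eq$slope - true_slope) / true_slope
  })
  expect_lt(median(rel_err), 0.10)
})

test_that("composition identity holds and calibrated methods agree", {
  anchors <- anchor_set(1.0, 2.0)
  cohort <- gen_calibration_cohort(cohort_params(
    yc_mean_std_suvr = 1.0, ad_mean_std_suvr = 2.0,
    method_slope = 1.4, method_intercept = -0.3, method_noise_sd = 0.04,
    seed = 13))
  eq <- fit_level2(cohort, anchors, "m")
  fit <- lm(standard_suvr ~ method_value, data = cohort)
  v <- seq(0.5, 3, by = 0.1)
  expect_equal(apply_equation(eq, v),
               standard_cl(coef(fit)[1] + coef(fit)[2] * v, anchors),
               ignore_attr = TRUE, tolerance = 1e-10)
  # two noiselessly affinely-related methods give identical CL values once
  # each is calibrated on the same cohort
  noiseless <- gen_calibration_cohort(cohort_params(method_noise_sd = 0,
                                                    seed = 14))
  m1 <- transform(noiseless, method_value = 1.2 * standard_suvr - 0.1)
  m2 <- transform(noiseless, method_value = 0.6 * standard_suvr + 0.9)
  cl1 <- apply_equation(fit_level2(m1, anchors, "m1"), m1$method_value)
  cl2 <- apply_equation(fit_level2(m2, anchors, "m2"), m2$method_value)
  expect_equal(cl1, cl2, tolerance = 1e-9)
})

test_that("apply/invert are exact affine inverses", {
  eq <- identity_equation()
  eq$slope <- 100; eq$intercept <- -100
  expect_equal(apply_equation(eq, 1.42), 42)
  x <- seq(-1, 3, by = 0.25)
  expect_equal(invert_equation(eq, apply_equation(eq, x)), x,
               tolerance = 1e-10)
})

test_that("calibration_report summarizes converted groups", {
  anchors <- anchor_set(1.05, 2.05)
  noiseless <- gen_calibration_cohort(cohort_params(method_noise_sd = 0,
                                                    yc_sd = 0, ad_sd = 0,
                                                    seed = 3))
  eq <- fit_level2(noiseless, anchors, "exact")
  qc <- calibration_report(eq, noiseless)
  expect_equal(qc$yc_mean_cl, 0, tolerance = 1e-8)
  expect_equal(qc$ad_mean_cl, 100, tolerance = 1e-8)
  # YC SD in CL is the affine image of the native YC SD
  cohort <- gen_calibration_cohort(cohort_params(seed = 23))
  eq2 <- fit_level2(cohort, anchors, "m")
  qc2 <- calibration_report(eq2, cohort)
  yc_native_sd <- sd(cohort$method_value[cohort$group == "YC"])
  expect_equal(qc2$yc_sd_cl, abs(eq2$slope) * yc_native_sd,
               tolerance = 1e-10)
  bad <- cohort[cohort$group == "YC", ]
  expect_error(calibration_report(eq2, bad), "AD")
})

test_that("noisy 18+18 cohorts keep the calibrated YC mean near 0", {
  anchors <- anchor_set(1.05, 2.05)
  dev <- sapply(1:20, function(s) {
    cohort <- gen_calibration_cohort(cohort_params(method_noise_sd = 0.05,
                                                   seed = 100 + s))
    qc <- calibration_report(fit_level2(cohort, anchors, "m"), cohort)
    qc$yc_mean_cl
  })
  expect_lt(abs(median(dev)), 2)
})

test_that("equations round-trip through JSON exactly", {
  anchors <- anchor_set(1.05, 2.05)
  cohort <- gen_calibration_cohort(cohort_params(seed = 41))
  eq <- fit_level2(cohort, anchors, "CL_3060_SUVr")
  path <- file.path(tempdir(), "eq.json")
  write_equation(eq, path)
  back <- read_equation(path)
  expect_identical(back$slope, eq$slope)
  expect_identical(back$intercept, eq$intercept)
  expect_identical(back$r_squared, eq$r_squared)
  expect_identical(back$method_label, eq$method_label)
  expect_equal(back$anchors$mu_yc, 1.05)
  unlink(path)
})

test_that("poor fits carry a quality flag", {
  set.seed(55)
  noisy <- data.frame(standard_suvr = rnorm(40, 1.5, 0.3),
                      method_value = rnorm(40, 1.5, 0.3))
  expect_warning(eq <- fit_level2(noisy, anchor_set(1, 2), "junk"),
                 "R-squared")
  expect_true(eq$quality_flag)
})
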