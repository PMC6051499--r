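# Synthetic cohort generators.
#
# Every downstream stage (calibration, thresholds, longitudinal statistics)
# is exercised on cohorts drawn from the generative models below, which mirror
# the statistical structure of the real calibration and observational data:
# a small paired calibration set (young controls vs Alzheimer patients whose
# method-specific values are affinely related to the standard SUVr plus noise),
# a cross-sectional mixture with an amyloid-negative mode near 0 CL and a
# positive mode near 60 CL, a two-visit longitudinal cohort with a
# baseline-dependent accumulation rate, reference-tissue-model time-activity
# curves, and regional mixing phantoms for partial-volume correction.

#' Parameters for a synthetic Centiloid calibration cohort
#'
#' Describes a paired calibration dataset of young controls (YC, assumed
#' amyloid-free) and Alzheimer-disease (AD) patients. Each subject has a
#' standard Centiloid SUVr drawn from a group-specific normal distribution and
#' a method-specific native value affinely related to the standard value plus
#' independent measurement noise. Defaults emulate an 18 + 18 calibration
#' subset with YC SUVr near 1.05 and AD SUVr near 2.05.
#'
#' @param n_yc,n_ad Group sizes (each at least 2).
#' @param yc_mean_std_suvr,ad_mean_std_suvr Group means of the standard SUVr;
#'   the AD mean must exceed the YC mean.
#' @param yc_sd,ad_sd Group standard deviations of the standard SUVr.
#' @param method_slope,method_intercept Affine relation mapping standard SUVr
#'   to the method's native value.
#' @param method_noise_sd Standard deviation of the native-scale measurement
#'   noise added on top of the affine relation.
#' @param seed Integer seed; fixing it reproduces the cohort bit-identically.
#' @return An object of class `cohort_params`.
#' @seealso [gen_calibration_cohort()]
#' @export
cohort_params <- function(n_yc = 18, n_ad = 18,
                          yc_mean_std_suvr = 1.05, ad_mean_std_suvr = 2.05,
                          yc_sd = 0.05, ad_sd = 0.20,
                          method_slope = 1, method_intercept = 0,
                          method_noise_sd = 0.05, seed = 1L) {
  check_scalar(n_yc, "n_yc", lower = 2, integer = TRUE)
  check_scalar(n_ad, "n_ad", lower = 2, integer = TRUE)
  check_scalar(yc_sd, "yc_sd", lower = 0)
  check_scalar(ad_sd, "ad_sd", lower = 0)
  check_scalar(method_noise_sd, "method_noise_sd", lower = 0)
  check_scalar(yc_mean_std_suvr, "yc_mean_std_suvr")
  check_scalar(ad_mean_std_suvr, "ad_mean_std_suvr")
  if (ad_mean_std_suvr <= yc_mean_std_suvr) {
    stop_input("'ad_mean_std_suvr' (%g) must exceed 'yc_mean_std_suvr' (%g)",
               ad_mean_std_suvr, yc_mean_std_suvr)
  }
  check_scalar(method_slope, "method_slope")
  check_scalar(method_intercept, "method_intercept")
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(n_yc = as.integer(n_yc), n_ad = as.integer(n_ad),
                 yc_mean_std_suvr = yc_mean_std_suvr,
                 ad_mean_std_suvr = ad_mean_std_suvr,
                 yc_sd = yc_sd, ad_sd = ad_sd,
                 method_slope = method_slope,
                 method_intercept = method_intercept,
                 method_noise_sd = method_noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

#' Generate a paired calibration cohort
#'
#' Draws `n_yc + n_ad` subjects with group labels, a standard Centiloid SUVr
#' per subject, and a method-specific native value
#' `method_slope * standard_suvr + method_intercept + noise`.
#'
#' @param params A [cohort_params()] object.
#' @return A data frame with columns `subject`, `group` (`"YC"`/`"AD"`),
#'   `standard_suvr` and `method_value`.
#' @examples
#' cohort <- gen_calibration_cohort(cohort_params(seed = 42))
#' table(cohort$group)
#' @export
gen_calibration_cohort <- function(params) {
  if (!inherits(params, "cohort_params")) {
    stop_input("'params' must be created with cohort_params()")
  }
  with_seed(params$seed, {
    n <- params$n_yc + params$n_ad
    group <- rep(c("YC", "AD"), c(params$n_yc, params$n_ad))
    std <- rnorm(n,
                 mean = ifelse(group == "YC", params$yc_mean_std_suvr,
                               params$ad_mean_std_suvr),
                 sd = ifelse(group == "YC", params$yc_sd, params$ad_sd))
    noise <- if (params$method_noise_sd > 0) {
      rnorm(n, 0, params$method_noise_sd)
    } else {
      numeric(n)
    }
    data.frame(subject = sprintf("sub-%03d", seq_len(n)),
               group = group,
               standard_suvr = std,
               method_value = params$method_slope * std +
                 params$method_intercept + noise,
               stringsAsFactors = FALSE)
  })
}

#' Baseline-dependent amyloid accumulation rate functions
#'
#' A parametric stand-in for the empirical annualized-rate-versus-baseline
#' curve: negative (apparent clearance or noise) at low burden, dipping to a
#' minimum, then crossing zero and rising once accumulation starts. Three
#' shapes are supported:
#' \describe{
#'   \item{`piecewise_linear`}{`max(floor, slope * (cl - zero))` with
#'     `parameters = c(slope, floor)`; `slope > 0`, `floor < 0`.}
#'   \item{`quadratic_dip`}{`a * (cl - x_min)^2 + c` with
#'     `parameters = c(a, x_min, c)`; `a > 0`, `c < 0`, so the upward zero
#'     crossing sits at `x_min + sqrt(-c / a)`.}
#'   \item{`logistic`}{`lo + (hi - lo) / (1 + exp(-k * (cl - x0)))` with
#'     `parameters = c(lo, hi, k, x0)`; `lo < 0 < hi`, `k > 0`.}
#' }
#' All shapes are evaluable on at least \[-30, 150\] CL.
#'
#' @param shape One of `"piecewise_linear"`, `"quadratic_dip"`, `"logistic"`,
#'   or `"constant"` (value given by `parameters[1]`, mainly for testing).
#' @param parameters Numeric vector of shape-specific coefficients (CL/yr and
#'   CL/yr per CL as appropriate; see Details).
#' @param true_zero_crossing Optional known upward zero crossing in CL; when
#'   omitted it is derived analytically where possible.
#' @return An object of class `rate_function` that can be called via
#'   [eval_rate()].
#' @export
rate_function <- function(shape = c("piecewise_linear", "quadratic_dip",
                                    "logistic", "constant"),
                          parameters, true_zero_crossing = NULL) {
  shape <- match.arg(shape)
  parameters <- as.numeric(parameters)
  need <- c(piecewise_linear = 2L, quadratic_dip = 3L, logistic = 4L,
            constant = 1L)[[shape]]
  if (length(parameters) != need || any(!is.finite(parameters))) {
    stop_input("shape '%s' needs %d finite parameters", shape, need)
  }
  derived <- switch(shape,
    piecewise_linear = {
      if (parameters[1] <= 0) stop_input("piecewise_linear slope must be > 0")
      if (is.null(true_zero_crossing)) {
        stop_input("piecewise_linear requires 'true_zero_crossing'")
      }
      true_zero_crossing
    },
    quadratic_dip = {
      a <- parameters[1]; cc <- parameters[3]
      if (a <= 0 || cc >= 0) stop_input("quadratic_dip needs a > 0 and c < 0")
      parameters[2] + sqrt(-cc / a)
    },
    logistic = {
      lo <- parameters[1]; hi <- parameters[2]; k <- parameters[3]
      x0 <- parameters[4]
      if (!(lo < 0 && hi > 0 && k > 0)) {
        stop_input("logistic needs lo < 0 < hi and k > 0")
      }
      x0 - log((hi - lo) / (-lo) - 1) / k
    },
    constant = NULL)
  if (!is.null(true_zero_crossing)) derived <- true_zero_crossing
  structure(list(shape = shape, parameters = parameters,
                 true_zero_crossing = derived),
            class = "rate_function")
}

#' Evaluate a rate function at baseline burden values
#'
#' @param rf A [rate_function()].
#' @param cl Numeric vector of baseline burdens in CL.
#' @return Annualized rates in CL/yr, same length as `cl`.
#' @export
eval_rate <- function(rf, cl) {
  if (!inherits(rf, "rate_function")) {
    stop_input("'rf' must be a rate_function")
  }
  p <- rf$parameters
  switch(rf$shape,
    constant = rep(p[1], length(cl)),
    piecewise_linear = pmax(p[2], p[1] * (cl - rf$true_zero_crossing)),
    quadratic_dip = p[1] * (cl - p[2])^2 + p[3],
    logistic = p[1] + (p[2] - p[1]) / (1 + exp(-p[3] * (cl - p[4]))))
}

#' Parameters for a synthetic two-visit longitudinal cohort
#'
#' @param n_subjects Number of subjects (at least 2).
#' @param baseline_distribution A mixture specification: list with numeric
#'   vectors `weights` (summing to 1), `means` (CL) and `sds` (CL). The default
#'   two-component mixture places an amyloid-negative mode near 0 CL and a
#'   positive mode near 60 CL.
#' @param interval_mean,interval_sd Follow-up interval distribution in years;
#'   intervals are drawn from a normal truncated below at `interval_min`.
#'   Defaults 3.2 and 1.5 yr.
#' @param interval_min Lower truncation bound for intervals (years).
#' @param rate_function A [rate_function()] giving the true annualized
#'   accumulation rate as a function of true baseline burden.
#' @param measurement_noise_sd Per-visit measurement noise SD in CL.
#' @param seed Integer seed.
#' @return An object of class `longitudinal_sim_params`.
#' @export
longitudinal_sim_params <- function(n_subjects = 243,
                                    baseline_distribution = list(
                                      weights = c(0.75, 0.25),
                                      means = c(0, 60),
                                      sds = c(6, 25)),
                                    interval_mean = 3.2, interval_sd = 1.5,
                                    interval_min = 0.5,
                                    rate_function = centiloidr::rate_function(
                                      "logistic", c(-0.5, 5, 0.15, 25)),
                                    measurement_noise_sd = 2.5,
                                    seed = 1L) {
  check_scalar(n_subjects, "n_subjects", lower = 2, integer = TRUE)
  check_scalar(interval_mean, "interval_mean", lower = 0, strict = TRUE)
  check_scalar(interval_sd, "interval_sd", lower = 0)
  check_scalar(interval_min, "interval_min", lower = 0)
  check_scalar(measurement_noise_sd, "measurement_noise_sd", lower = 0)
  check_scalar(seed, "seed", integer = TRUE)
  bd <- baseline_distribution
  if (!is.list(bd) || !all(c("weights", "means", "sds") %in% names(bd)) ||
      length(unique(lengths(bd[c("weights", "means", "sds")]))) != 1L) {
    stop_input("'baseline_distribution' needs equal-length weights/means/sds")
  }
  if (abs(sum(bd$weights) - 1) > 1e-8 || any(bd$weights < 0)) {
    stop_input("'baseline_distribution$weights' must be nonnegative and sum to 1")
  }
  if (any(bd$sds < 0)) stop_input("'baseline_distribution$sds' must be >= 0")
  if (!inherits(rate_function, "rate_function")) {
    stop_input("'rate_function' must be a rate_function object")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 baseline_distribution = bd,
                 interval_mean = interval_mean, interval_sd = interval_sd,
                 interval_min = interval_min,
                 rate_function = rate_function,
                 measurement_noise_sd = measurement_noise_sd,
                 seed = as.integer(seed)),
            class = "longitudinal_sim_params")
}

# Normal draws truncated below at `lower`, by rejection (the truncation point
# sits far in the lower tail for realistic follow-up intervals, so rejection
# is cheap and exact).
rtruncnorm_lower <- function(n, mean, sd, lower) {
  out <- rnorm(n, mean, sd)
  bad <- which(out <= lower)
  guard <- 0L
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lower]
    guard <- guard + 1L
    if (guard > 10000L) stop_input("interval truncation failed to converge")
  }
  out
}

#' Generate a two-visit longitudinal cohort
#'
#' True baselines are drawn from the configured mixture; the true follow-up is
#' a single Euler step `baseline + rate(baseline) * interval` (the rate is
#' applied at baseline over the whole interval, matching an annualized-rate
#' analysis rather than an integrated trajectory). Observed values add
#' independent per-visit noise. Intervals are truncated-normal and strictly
#' positive by construction.
#'
#' @param params A [longitudinal_sim_params()] object.
#' @return A data frame with columns `subject`, `baseline_true`,
#'   `followup_true`, `baseline_cl`, `followup_cl` and `interval` (years).
#' @export
gen_longitudinal_cohort <- function(params) {
  if (!inherits(params, "longitudinal_sim_params")) {
    stop_input("'params' must be created with longitudinal_sim_params()")
  }
  with_seed(params$seed, {
    n <- params$n_subjects
    bd <- params$baseline_distribution
    comp <- sample.int(length(bd$weights), n, replace = TRUE,
                       prob = bd$weights)
    baseline_true <- rnorm(n, bd$means[comp], bd$sds[comp])
    interval <- rtruncnorm_lower(n, params$interval_mean, params$interval_sd,
                                 params$interval_min)
    followup_true <- baseline_true +
      eval_rate(params$rate_function, baseline_true) * interval
    noise_sd <- params$measurement_noise_sd
    baseline_cl <- baseline_true +
      if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
    followup_cl <- followup_true +
      if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
    data.frame(subject = sprintf("sub-%03d", seq_len(n)),
               baseline_true = baseline_true, followup_true = followup_true,
               baseline_cl = baseline_cl, followup_cl = followup_cl,
               interval = interval, stringsAsFactors = FALSE)
  })
}

#' Generate a cross-sectional Centiloid cohort from a mixture
#'
#' Convenience generator for an observational-cohort-like marginal
#' distribution: a mixture of normals (default: negative mode near 0 CL,
#' positive mode near 60 CL) plus measurement noise.
#'
#' @param n Number of subjects.
#' @param mixture List with `weights`, `means`, `sds` as in
#'   [longitudinal_sim_params()].
#' @param measurement_noise_sd Measurement noise SD in CL.
#' @param seed Integer seed.
#' @return Data frame with columns `subject`, `true_cl`, `cl`.
#' @export
gen_cross_sectional_cohort <- function(n = 590,
                                       mixture = list(weights = c(0.75, 0.25),
                                                      means = c(0, 60),
                                                      sds = c(6, 25)),
                                       measurement_noise_sd = 2.5,
                                       seed = 1L) {
  check_scalar(n, "n", lower = 1, integer = TRUE)
  check_scalar(measurement_noise_sd, "measurement_noise_sd", lower = 0)
  with_seed(seed, {
    comp <- sample.int(length(mixture$weights), n, replace = TRUE,
                       prob = mixture$weights)
    true_cl <- rnorm(n, mixture$means[comp], mixture$sds[comp])
    cl <- true_cl + if (measurement_noise_sd > 0) {
      rnorm(n, 0, measurement_noise_sd)
    } else 0
    data.frame(subject = sprintf("sub-%03d", seq_len(n)),
               true_cl = true_cl, cl = cl, stringsAsFactors = FALSE)
  })
}

#' Simplified reference tissue model (SRTM) parameters
#'
#' @param R1 Relative tracer delivery (target K1 over reference K1).
#' @param k2 Target-tissue efflux rate constant (1/min), > 0.
#' @param bp_true True non-displaceable binding potential (>= 0); the
#'   distribution volume ratio is `1 + bp_true`.
#' @param frame_mid_times Strictly increasing frame mid-times (minutes).
#' @param frame_durations Frame durations (minutes), > 0.
#' @param reference_input Reference-region activity over time: either a
#'   function of `t` (minutes) or a list, one of
#'   `list(type = "constant", value =)`,
#'   `list(type = "biexp", A =, lambda1 =, lambda2 =)` giving
#'   `A * (exp(-lambda1 t) - exp(-lambda2 t))` (rise then washout). The
#'   default emulates slow-clearing tracer kinetics in a reference region.
#' @return An object of class `srtm_params`.
#' @export
srtm_params <- function(R1 = 0.9, k2 = 0.2, bp_true = 0.5,
                        frame_mid_times = seq(2.5, 87.5, by = 5),
                        frame_durations = rep(5, length(frame_mid_times)),
                        reference_input = list(type = "biexp", A = 10,
                                               lambda1 = 0.005,
                                               lambda2 = 0.35)) {
  check_scalar(R1, "R1", lower = 0, strict = TRUE)
  check_scalar(k2, "k2", lower = 0, strict = TRUE)
  check_scalar(bp_true, "bp_true", lower = 0)
  if (length(frame_mid_times) < 2 || any(diff(frame_mid_times) <= 0)) {
    stop_input("'frame_mid_times' must be strictly increasing (length >= 2)")
  }
  if (length(frame_durations) != length(frame_mid_times) ||
      any(frame_durations <= 0)) {
    stop_input("'frame_durations' must be positive, one per frame")
  }
  structure(list(R1 = R1, k2 = k2, bp_true = bp_true,
                 frame_mid_times = as.numeric(frame_mid_times),
                 frame_durations = as.numeric(frame_durations),
                 reference_input = reference_input),
            class = "srtm_params")
}

reference_input_fun <- function(spec) {
  if (is.function(spec)) return(spec)
  if (!is.list(spec) || is.null(spec$type)) {
    stop_input("'reference_input' must be a function or a typed list")
  }
  switch(spec$type,
    constant = {
      v <- spec$value
      function(t) rep(v, length(t))
    },
    biexp = {
      A <- spec$A; l1 <- spec$lambda1; l2 <- spec$lambda2
      function(t) A * (exp(-l1 * t) - exp(-l2 * t))
    },
    stop_input("unknown reference_input type '%s'", spec$type))
}

#' Simulate SRTM target and reference time-activity curves
#'
#' Solves the simplified reference tissue model
#' `Ct = R1 * Cr + (k2 - R1 * k2a) * (Cr conv exp(-k2a t))` with
#' `k2a = k2 / (1 + BP)` on a dense time grid (exponential-kernel convolution
#' with trapezoidal increments), then samples at the frame mid-times. With
#' `bp_true = 0` and `R1 = 1` the target equals the reference exactly; with a
#' constant reference the target tends to `(1 + BP) * reference`.
#'
#' @param params An [srtm_params()] object.
#' @param dt Dense-grid step in minutes (default 0.02; truncation error is far
#'   below the tolerances used anywhere downstream).
#' @return A list with elements `target` and `reference`, both [tac()] objects
#'   on the frame grid of `params`.
#' @export
gen_srtm_tacs <- function(params, dt = 0.02) {
  if (!inherits(params, "srtm_params")) {
    stop_input("'params' must be created with srtm_params()")
  }
  cr_fun <- reference_input_fun(params$reference_input)
  tmax <- max(params$frame_mid_times)
  tt <- seq(0, tmax, by = dt)
  if (tt[length(tt)] < tmax) tt <- c(tt, tmax)
  cr <- cr_fun(tt)
  k2a <- params$k2 / (1 + params$bp_true)
  # I(t) = int_0^t Cr(u) exp(-k2a (t - u)) du via the exact one-step recursion
  # for the exponential kernel with trapezoidal quadrature of the source term.
  n <- length(tt)
  conv <- numeric(n)
  damp <- exp(-k2a * diff(tt))
  for (i in 2:n) {
    h <- tt[i] - tt[i - 1]
    conv[i] <- conv[i - 1] * damp[i - 1] +
      h / 2 * (cr[i] + cr[i - 1] * damp[i - 1])
  }
  ct <- params$R1 * cr + (params$k2 - params$R1 * k2a) * conv
  mid <- params$frame_mid_times
  list(target = tac(mid, params$frame_durations,
                    approx(tt, ct, xout = mid)$y),
       reference = tac(mid, params$frame_durations,
                       approx(tt, cr, xout = mid)$y))
}

#' Regional mixing phantom specification
#'
#' Describes ground truth for testing the mixing-matrix partial-volume
#' correction: true regional means and a row-stochastic mixing matrix whose
#' rows describe how scanner blur redistributes signal between regions.
#'
#' @param true_means Nonnegative true regional activities.
#' @param mixing_matrix Square nonnegative matrix, rows summing to 1 within
#'   1e-9, dimension equal to `length(true_means)`.
#' @param noise_sd Additive observation noise SD (>= 0).
#' @param seed Integer seed used when `noise_sd > 0`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(true_means, mixing_matrix, noise_sd = 0, seed = 1L) {
  true_means <- as.numeric(true_means)
  if (any(!is.finite(true_means)) || any(true_means < 0)) {
    stop_input("'true_means' must be finite and nonnegative")
  }
  mixing_matrix <- as.matrix(mixing_matrix)
  k <- length(true_means)
  if (!all(dim(mixing_matrix) == k)) {
    stop_input("'mixing_matrix' must be %d x %d", k, k)
  }
  if (any(mixing_matrix < 0)) stop_input("'mixing_matrix' must be nonnegative")
  rs <- rowSums(mixing_matrix)
  if (any(abs(rs - 1) > 1e-9)) {
    stop_input("'mixing_matrix' rows must sum to 1 (max deviation %g)",
               max(abs(rs - 1)))
  }
  check_scalar(noise_sd, "noise_sd", lower = 0)
  structure(list(n_regions = k, true_means = true_means,
                 mixing_matrix = mixing_matrix, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate observed regional means from a mixing phantom
#'
#' @param spec A [phantom_spec()] object.
#' @return Numeric vector `mixing_matrix %*% true_means + noise`.
#' @export
gen_pvc_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    stop_input("'spec' must be created with phantom_spec()")
  }
  obs <- drop(spec$mixing_matrix %*% spec$true_means)
  if (spec$noise_sd > 0) {
    obs <- obs + with_seed(spec$seed, rnorm(length(obs), 0, spec$noise_sd))
  }
  obs
}

#' Write a generated cohort with a JSON parameter sidecar
#'
#' Writes the cohort as comma-separated UTF-8 text with a header row, plus a
#' `<path>.json` sidecar recording the generating parameters (including the
#' seed) so any table can be regenerated exactly.
#'
#' @param cohort Data frame as returned by one of the generators.
#' @param path Output CSV path.
#' @param params The parameter object used to generate `cohort` (optional).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, params = NULL) {
  write.csv(cohort, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  if (!is.null(params)) {
    side <- unclass(params)
    if (inherits(params$rate_function, "rate_function")) {
      side$rate_function <- unclass(params$rate_function)
    }
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}
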