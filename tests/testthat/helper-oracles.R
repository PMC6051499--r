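# Shared fixtures and independent oracles, all built in code.

const_tac <- function(value, mid = seq(2.5, 87.5, by = 5), dur = 5) {
  tac(mid, rep(dur, length(mid)), rep(value, length(mid)))
}

# Independent SRTM oracle: classical RK4 on the model ODE
#   dCt/dt = R1 dCr/dt + k2 Cr - k2a Ct,   k2a = k2 / (1 + BP),
# with the reference curve and its derivative supplied analytically. This
# shares no code with the package's exponential-kernel convolution.
srtm_rk4 <- function(R1, k2, bp, t_out, cr_fun, dcr_fun, dt = 0.01) {
  k2a <- k2 / (1 + bp)
  f <- function(t, ct) R1 * dcr_fun(t) + k2 * cr_fun(t) - k2a * ct
  tmax <- max(t_out)
  n <- ceiling(tmax / dt)
  ct <- 0
  tt <- 0
  ts <- numeric(n + 1)
  cts <- numeric(n + 1)
  for (i in seq_len(n)) {
    h <- min(dt, tmax - tt)
    k_1 <- f(tt, ct)
    k_2 <- f(tt + h / 2, ct + h / 2 * k_1)
    k_3 <- f(tt + h / 2, ct + h / 2 * k_2)
    k_4 <- f(tt + h, ct + h * k_3)
    ct <- ct + h / 6 * (k_1 + 2 * k_2 + 2 * k_3 + k_4)
    tt <- tt + h
    ts[i + 1] <- tt
    cts[i + 1] <- ct
  }
  approx(ts, cts, xout = t_out)$y
}

biexp_cr <- function(A, l1, l2) {
  list(cr = function(t) A * (exp(-l1 * t) - exp(-l2 * t)),
       dcr = function(t) A * (-l1 * exp(-l1 * t) + l2 * exp(-l2 * t)))
}

# Closed-form SRTM solution for a single-exponential reference input
#   Cr(t) = A exp(-l t):
#   Ct(t) = R1 Cr + (k2 - R1 k2a) A (exp(-l t) - exp(-k2a t)) / (k2a - l)
srtm_closed_single_exp <- function(R1, k2, bp, A, l, t) {
  k2a <- k2 / (1 + bp)
  R1 * A * exp(-l * t) +
    (k2 - R1 * k2a) * A * (exp(-l * t) - exp(-k2a * t)) / (k2a - l)
}

default_test_pairs <- function(seed = 1, n = 243, noise = 2.5,
                               rf = rate_function("logistic",
                                                  c(-0.5, 5, 0.15, 25))) {
  lp <- longitudinal_sim_params(n_subjects = n, rate_function = rf,
                                measurement_noise_sd = noise, seed = seed)
  lc <- gen_longitudinal_cohort(lp)
  longitudinal_pairs(lc$subject, lc$baseline_cl, lc$followup_cl, lc$interval)
}

make_curve <- function(grid, fitted) {
  structure(list(grid = as.integer(grid), fitted_rate = fitted,
                 lower_band = rep(NA_real_, length(grid)),
                 upper_band = rep(NA_real_, length(grid)),
                 span = 0.75, n_boot = 0L, ci_level = 0.95,
                 n_pairs = NA_integer_),
            class = "loess_rate_curve")
}

identity_equation <- function(label = "identity") {
  # CL(v) = v: built from a noiseless calibration where the method value is
  # already on the Centiloid scale of anchors (1, 2) scaled by 1/100.
  structure(list(method_label = label, slope = 1, intercept = 0,
                 r_squared = 1, n_fit = 36L,
                 anchors = anchor_set(0, 100), quality_flag = FALSE),
            class = "conversion_equation")
}
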