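# Amyloid-positivity threshold estimators.
#
# Three estimators are provided, all reported in Centiloid units:
#   1. conversion of an empirical native-scale cutoff through the method's
#      level-2 equation;
#   2. the specificity threshold — the 95th percentile of the young-control
#      distribution, above which a truly amyloid-free subject is unlikely;
#   3. a modified "reliable worsening" rule — the baseline burden at which
#      the LOESS-smoothed annualized rate-of-change curve rises above zero
#      after passing its minimum, so the returned threshold always
#      corresponds to a positive accumulation rate.

#' Construct a table of longitudinal visit pairs
#'
#' @param subject Subject identifiers.
#' @param baseline_cl,followup_cl Centiloid values at the two visits.
#' @param interval Visit interval in years, > 0.
#' @return A data frame of class `longitudinal_pairs`.
#' @export
longitudinal_pairs <- function(subject, baseline_cl, followup_cl, interval) {
  n <- length(baseline_cl)
  if (length(followup_cl) != n || length(interval) != n ||
      length(subject) != n) {
    stop_input("all pair columns must have equal length")
  }
  if (any(!is.finite(interval)) || any(interval <= 0)) {
    stop_input("'interval' must be positive and finite for every pair")
  }
  structure(data.frame(subject = as.character(subject),
                       baseline_cl = as.numeric(baseline_cl),
                       followup_cl = as.numeric(followup_cl),
                       interval = as.numeric(interval),
                       stringsAsFactors = FALSE),
            class = c("longitudinal_pairs", "data.frame"))
}

as_pairs <- function(pairs) {
  if (!is.data.frame(pairs) ||
      !all(c("baseline_cl", "followup_cl", "interval") %in% names(pairs))) {
    stop_input("'pairs' needs columns baseline_cl, followup_cl, interval")
  }
  pairs
}

#' Annualized rate of change
#'
#' @param pairs Data frame with columns `baseline_cl`, `followup_cl`,
#'   `interval` (years).
#' @return `(followup_cl - baseline_cl) / interval`, in CL/yr.
#' @export
annualized_rate <- function(pairs) {
  pairs <- as_pairs(pairs)
  if (any(pairs$interval <= 0)) {
    stop_input("'interval' must be > 0 for every pair")
  }
  (pairs$followup_cl - pairs$baseline_cl) / pairs$interval
}

#' Convert an empirical native-scale threshold to Centiloid
#'
#' @param eq A `conversion_equation` from [fit_level2()].
#' @param native_threshold Threshold on the method's native scale (for
#'   example a mean cortical binding potential of 0.18).
#' @return The threshold in CL.
#' @export
convert_native_threshold <- function(eq, native_threshold) {
  check_scalar(native_threshold, "native_threshold")
  apply_equation(eq, native_threshold)
}

#' Specificity threshold from young controls
#'
#' Empirical percentile (default 95th) of the amyloid-burden values of a
#' young-control sample, using linear interpolation between order statistics
#' (the type-7 quantile definition, R's default): with sorted values
#' `x_(1) <= ... <= x_(n)`, the p-quantile is the value at fractional order
#' `1 + p (n - 1)`.
#'
#' @param yc_values_cl Young-control values in CL, n >= 5.
#' @param percentile Percentile as a fraction in (0, 1); default 0.95.
#' @return The threshold in CL.
#' @export
specificity_threshold <- function(yc_values_cl, percentile = 0.95) {
  if (length(yc_values_cl) < 5) {
    stop_input("specificity threshold needs at least 5 values (got %d)",
               length(yc_values_cl))
  }
  check_scalar(percentile, "percentile", lower = 0, upper = 1, strict = TRUE)
  unname(quantile(yc_values_cl, percentile, type = 7, names = FALSE))
}

loess_fit_predict <- function(baseline, rate, span, grid) {
  fit <- loess(rate ~ baseline, span = span, degree = 1,
               family = "gaussian",
               control = loess.control(surface = "direct"))
  pred <- unname(predict(fit, newdata = data.frame(baseline = grid)))
  pred[grid < min(baseline) | grid > max(baseline)] <- NA_real_
  pred
}

#' LOESS-smoothed annualized-rate-versus-baseline curve
#'
#' Smooths the per-subject annualized rate of change against baseline burden
#' with locally linear LOESS (tricube weights) and evaluates the fit on an
#' integer Centiloid grid. Pointwise confidence bands come from a subject
#' bootstrap: pairs are resampled with replacement, the curve is refit, and
#' the bands are percentile intervals of the refitted curves at each grid
#' point. Grid points outside the observed baseline range are reported as
#' `NA` (never extrapolated).
#'
#' @param pairs Longitudinal pairs (>= 20 rows).
#' @param span LOESS span in (0, 1]; default 0.75.
#' @param grid_min,grid_max Integer grid bounds in CL; by default the grid
#'   spans the central 98% of the baseline values, avoiding edge-dominated
#'   LOESS behavior.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param ci_level Confidence level for the percentile bands (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @param keep_boot Keep the matrix of bootstrap curves (needed for a
#'   bootstrap band on the reliable-worsening threshold).
#' @return An object of class `loess_rate_curve`: list with `grid`,
#'   `fitted_rate`, `lower_band`, `upper_band`, `span`, `n_boot`, `ci_level`,
#'   `n_pairs`, and optionally `boot` (n_boot x length(grid)).
#' @export
loess_rate_curve <- function(pairs, span = 0.75, grid_min = NULL,
                             grid_max = NULL, n_boot = 1000, ci_level = 0.95,
                             seed = 1L, keep_boot = FALSE) {
  pairs <- as_pairs(pairs)
  if (nrow(pairs) < 20) {
    stop_input("LOESS rate curve needs >= 20 pairs (got %d)", nrow(pairs))
  }
  check_scalar(span, "span", lower = 0, upper = 1, strict = FALSE)
  if (span <= 0) stop_input("'span' must be in (0, 1]")
  check_scalar(n_boot, "n_boot", lower = 0, integer = TRUE)
  check_scalar(ci_level, "ci_level", lower = 0, upper = 1, strict = TRUE)
  baseline <- pairs$baseline_cl
  rate <- annualized_rate(pairs)
  if (is.null(grid_min)) grid_min <- ceiling(quantile(baseline, 0.01, names = FALSE))
  if (is.null(grid_max)) grid_max <- floor(quantile(baseline, 0.99, names = FALSE))
  if (grid_min >= grid_max) {
    stop_input("grid_min (%g) must be < grid_max (%g)", grid_min, grid_max)
  }
  grid <- seq(ceiling(grid_min), floor(grid_max), by = 1L)
  fitted <- loess_fit_predict(baseline, rate, span, grid)
  lower <- upper <- rep(NA_real_, length(grid))
  boot <- NULL
  if (n_boot > 0) {
    boot <- with_seed(seed, {
      m <- matrix(NA_real_, nrow = n_boot, ncol = length(grid))
      n <- length(baseline)
      for (b in seq_len(n_boot)) {
        idx <- sample.int(n, n, replace = TRUE)
        m[b, ] <- tryCatch(
          loess_fit_predict(baseline[idx], rate[idx], span, grid),
          error = function(e) rep(NA_real_, length(grid)))
      }
      m
    })
    alpha <- (1 - ci_level) / 2
    lower <- apply(boot, 2, quantile, probs = alpha, na.rm = TRUE,
                   names = FALSE)
    upper <- apply(boot, 2, quantile, probs = 1 - alpha, na.rm = TRUE,
                   names = FALSE)
  }
  out <- list(grid = as.integer(grid), fitted_rate = fitted,
              lower_band = lower, upper_band = upper, span = span,
              n_boot = as.integer(n_boot), ci_level = ci_level,
              n_pairs = nrow(pairs))
  if (keep_boot) out$boot <- boot
  structure(out, class = "loess_rate_curve")
}

#' @export
print.loess_rate_curve <- function(x, ...) {
  cat(sprintf("LOESS rate curve: grid %d..%d CL (%d points), span %.2f, %d bootstrap resamples\n",
              min(x$grid), max(x$grid), length(x$grid), x$span, x$n_boot))
  invisible(x)
}

#' Export a rate curve as a plain table
#'
#' @param curve A `loess_rate_curve`.
#' @return Data frame with columns `grid_cl`, `fitted_rate`, `lower_band`,
#'   `upper_band`.
#' @export
curve_table <- function(curve) {
  stopifnot(inherits(curve, "loess_rate_curve"))
  data.frame(grid_cl = curve$grid, fitted_rate = curve$fitted_rate,
             lower_band = curve$lower_band, upper_band = curve$upper_band)
}

rw_from_fit <- function(grid, fitted) {
  ok <- which(!is.na(fitted))
  if (length(ok) < 3) return(NA_integer_)
  m <- ok[which.min(fitted[ok])]
  cand <- ok[ok >= m & fitted[ok] > 0]
  if (!length(cand)) NA_integer_ else as.integer(grid[min(cand)])
}

#' Modified reliable-worsening threshold
#'
#' Scans the fitted rate curve for the minimum of the smoothed annualized
#' rate, then returns the smallest grid Centiloid at or after the minimum
#' with a strictly positive fitted rate. A grid point exactly at zero does
#' not qualify: by construction the threshold never corresponds to a
#' non-positive accumulation rate. If the curve is positive already at its
#' minimum (everywhere-positive curve) the minimum's grid value is returned
#' with a warning; if no point after the minimum is positive, `NA` is
#' returned with a diagnostic warning.
#'
#' @param curve A `loess_rate_curve` with at least 3 supported (non-`NA`)
#'   grid points.
#' @return Integer Centiloid threshold, or `NA_integer_` when the curve
#'   never rises above zero after its minimum.
#' @export
rw_threshold <- function(curve) {
  stopifnot(inherits(curve, "loess_rate_curve"))
  ok <- which(!is.na(curve$fitted_rate))
  if (length(ok) < 3) {
    stop_input("reliable-worsening threshold needs >= 3 supported grid points")
  }
  m <- ok[which.min(curve$fitted_rate[ok])]
  if (curve$fitted_rate[m] > 0) {
    warning("fitted rate curve is positive at its minimum; returning the minimum's grid point",
            call. = FALSE)
  }
  res <- rw_from_fit(curve$grid, curve$fitted_rate)
  if (is.na(res)) {
    warning("fitted rate never rises above zero after its minimum; no reliable-worsening threshold",
            call. = FALSE)
  }
  res
}

#' Assemble the three positivity thresholds for one method
#'
#' @param eq A `conversion_equation` (used for the empirical conversion and
#'   the method label).
#' @param yc_values_cl Young-control values in CL for the specificity
#'   threshold.
#' @param pairs Longitudinal pairs for the reliable-worsening threshold.
#' @param config List of options: `native_threshold` (native-scale empirical
#'   cutoff, or `NULL` to skip), `percentile` (default 0.95), `span`,
#'   `n_boot`, `ci_level`, `grid_min`, `grid_max`, `seed`.
#' @return An object of class `threshold_set`: `method_label`,
#'   `empirical_cl` (or `NA`), `specificity_cl`, `rw_cl` (integer CL),
#'   `rw_band` (integer pair from the bootstrap distribution of the
#'   reliable-worsening threshold, or `NULL` when bootstrap is off), and the
#'   fitted `curve`.
#' @export
build_threshold_set <- function(eq, yc_values_cl, pairs, config = list()) {
  stopifnot(inherits(eq, "conversion_equation"))
  cfg <- utils::modifyList(list(native_threshold = NULL, percentile = 0.95,
                                span = 0.75, n_boot = 1000, ci_level = 0.95,
                                grid_min = NULL, grid_max = NULL, seed = 1L),
                           config)
  empirical <- if (is.null(cfg$native_threshold)) NA_real_ else
    convert_native_threshold(eq, cfg$native_threshold)
  spec_cl <- specificity_threshold(yc_values_cl, cfg$percentile)
  curve <- loess_rate_curve(pairs, span = cfg$span, grid_min = cfg$grid_min,
                            grid_max = cfg$grid_max, n_boot = cfg$n_boot,
                            ci_level = cfg$ci_level, seed = cfg$seed,
                            keep_boot = TRUE)
  rw <- suppressWarnings(rw_threshold(curve))
  rw_band <- NULL
  if (!is.null(curve$boot) && nrow(curve$boot) > 0) {
    boot_rw <- apply(curve$boot, 1, rw_from_fit, grid = curve$grid)
    boot_rw <- boot_rw[!is.na(boot_rw)]
    if (length(boot_rw) >= 10) {
      alpha <- (1 - cfg$ci_level) / 2
      rw_band <- as.integer(round(quantile(boot_rw, c(alpha, 1 - alpha),
                                           names = FALSE)))
    }
  }
  curve$boot <- NULL
  structure(list(method_label = eq$method_label, empirical_cl = empirical,
                 specificity_cl = spec_cl, rw_cl = rw, rw_band = rw_band,
                 curve = curve),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("Positivity thresholds for %s:\n", x$method_label))
  cat(sprintf("  empirical (converted): %s CL\n",
              if (is.na(x$empirical_cl)) "-" else sprintf("%.1f", x$empirical_cl)))
  cat(sprintf("  specificity:           %.1f CL\n", x$specificity_cl))
  cat(sprintf("  reliable worsening:    %s CL%s\n",
              if (is.na(x$rw_cl)) "-" else x$rw_cl,
              if (is.null(x$rw_band)) "" else
                sprintf(" [%d, %d]", x$rw_band[1], x$rw_band[2])))
  invisible(x)
}
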