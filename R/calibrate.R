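# Centiloid anchor equation and level-2 calibration.
#
# The Centiloid scale maps amyloid burden onto a 0-100 scale anchored at the
# mean standard SUVr of amyloid-free young controls (0 CL) and the mean of
# typical Alzheimer patients (100 CL). A non-standard quantification method is
# brought onto the scale by "level-2" calibration: regress the standard SUVr
# on the method's native value in a paired calibration cohort, then compose
# the fitted affine map with the anchor equation.

#' Centiloid anchor points
#'
#' @param mu_yc Mean standard SUVr of the young-control group (maps to 0 CL).
#' @param mu_ad Mean standard SUVr of the AD group (maps to 100 CL); must
#'   exceed `mu_yc`.
#' @return An object of class `anchor_set`.
#' @export
anchor_set <- function(mu_yc, mu_ad) {
  check_scalar(mu_yc, "mu_yc")
  check_scalar(mu_ad, "mu_ad")
  if (mu_ad <= mu_yc) {
    stop_input("'mu_ad' (%g) must exceed 'mu_yc' (%g)", mu_ad, mu_yc)
  }
  structure(list(mu_yc = mu_yc, mu_ad = mu_ad), class = "anchor_set")
}

#' Standard Centiloid transform
#'
#' `CL = 100 * (value - mu_yc) / (mu_ad - mu_yc)`: exactly 0 at the
#' young-control anchor and exactly 100 at the AD anchor.
#'
#' @param value Standard Centiloid SUVr value(s).
#' @param anchors An [anchor_set()].
#' @return Centiloid value(s).
#' @export
standard_cl <- function(value, anchors) {
  stopifnot(inherits(anchors, "anchor_set"))
  100 * (value - anchors$mu_yc) / (anchors$mu_ad - anchors$mu_yc)
}

#' Estimate anchor points from group samples
#'
#' @param yc_values,ad_values Standard SUVr samples for the young-control and
#'   AD groups (each n >= 2).
#' @return An [anchor_set()] of the two group means.
#' @export
fit_anchors <- function(yc_values, ad_values) {
  if (length(yc_values) < 2 || length(ad_values) < 2) {
    stop_input("each anchor group needs at least 2 values")
  }
  mu_yc <- mean(yc_values)
  mu_ad <- mean(ad_values)
  if (mu_ad <= mu_yc) {
    stop_input("AD group mean (%g) does not exceed YC group mean (%g); anchors undefined",
               mu_ad, mu_yc)
  }
  anchor_set(mu_yc, mu_ad)
}

#' Level-2 Centiloid calibration
#'
#' Fits ordinary least squares with the standard SUVr as response and the
#' method's native value as predictor, `shat(v) = a * v + b`, and composes it
#' with [standard_cl()], giving the per-method conversion
#' `CL(v) = slope * v + intercept` with `slope = 100 a / (mu_ad - mu_yc)` and
#' `intercept = 100 (b - mu_yc) / (mu_ad - mu_yc)`. Fits with R-squared below
#' 0.70 are flagged (`quality_flag = TRUE`) with a warning but still returned.
#'
#' @param paired Data frame with columns `method_value` and `standard_suvr`
#'   (e.g. from [gen_calibration_cohort()]), n >= 4.
#' @param anchors An [anchor_set()].
#' @param method_label Label stored on the equation.
#' @return An object of class `conversion_equation` with fields
#'   `method_label`, `slope`, `intercept`, `r_squared`, `n_fit`, `anchors`,
#'   `quality_flag`.
#' @export
fit_level2 <- function(paired, anchors, method_label = "method") {
  stopifnot(inherits(anchors, "anchor_set"))
  if (!is.data.frame(paired) ||
      !all(c("method_value", "standard_suvr") %in% names(paired))) {
    stop_input("'paired' needs columns 'method_value' and 'standard_suvr'")
  }
  n <- nrow(paired)
  if (n < 4) stop_input("level-2 calibration needs n >= 4 pairs (got %d)", n)
  if (sd(paired$method_value) == 0) {
    stop_input("degenerate fit: 'method_value' is constant")
  }
  fit <- lm(standard_suvr ~ method_value, data = paired)
  a <- unname(coef(fit)[2])
  b <- unname(coef(fit)[1])
  # computed directly so noiseless (numerically perfect) fits stay silent
  tss <- sum((paired$standard_suvr - mean(paired$standard_suvr))^2)
  r2 <- 1 - sum(stats::residuals(fit)^2) / tss
  span <- anchors$mu_ad - anchors$mu_yc
  flag <- r2 < 0.70
  if (flag) {
    warning(sprintf("level-2 fit for '%s' has R-squared %.3f < 0.70",
                    method_label, r2), call. = FALSE)
  }
  structure(list(method_label = method_label,
                 slope = 100 * a / span,
                 intercept = 100 * (b - anchors$mu_yc) / span,
                 r_squared = r2, n_fit = n, anchors = anchors,
                 quality_flag = flag),
            class = "conversion_equation")
}

#' @export
print.conversion_equation <- function(x, ...) {
  cat(sprintf("Centiloid conversion for %s: CL = %.4f * v %+.4f (R2 = %.4f, n = %d)%s\n",
              x$method_label, x$slope, x$intercept, x$r_squared, x$n_fit,
              if (x$quality_flag) " [low-quality fit]" else ""))
  invisible(x)
}

#' Apply a conversion equation
#'
#' @param eq A `conversion_equation` from [fit_level2()].
#' @param values Native method values.
#' @return Centiloid values, elementwise `slope * v + intercept`.
#' @export
apply_equation <- function(eq, values) {
  stopifnot(inherits(eq, "conversion_equation"))
  eq$slope * values + eq$intercept
}

#' Invert a conversion equation
#'
#' @param eq A `conversion_equation`.
#' @param cl Centiloid values.
#' @return Native method values `(cl - intercept) / slope`.
#' @export
invert_equation <- function(eq, cl) {
  stopifnot(inherits(eq, "conversion_equation"))
  (cl - eq$intercept) / eq$slope
}

#' Calibration quality-control summary
#'
#' Converts a paired calibration cohort with the fitted equation and reports
#' the young-control mean and SD and the AD mean in Centiloid units, plus the
#' fit R-squared — the per-method row of a calibration summary table. The YC
#' SD in CL indexes the inter-individual variability of the method
#' (`V_YC`).
#'
#' @param eq A `conversion_equation`.
#' @param cohort Data frame with columns `group` (`"YC"`/`"AD"`) and
#'   `method_value`.
#' @return An object of class `calibration_qc`: list with `method_label`,
#'   `yc_mean_cl`, `yc_sd_cl`, `ad_mean_cl`, `r_squared`.
#' @export
calibration_report <- function(eq, cohort) {
  stopifnot(inherits(eq, "conversion_equation"))
  if (!is.data.frame(cohort) ||
      !all(c("group", "method_value") %in% names(cohort))) {
    stop_input("'cohort' needs columns 'group' and 'method_value'")
  }
  missing <- setdiff(c("YC", "AD"), unique(cohort$group))
  if (length(missing)) {
    stop_input("cohort is missing group(s): %s", paste(missing, collapse = ", "))
  }
  cl <- apply_equation(eq, cohort$method_value)
  yc <- cl[cohort$group == "YC"]
  ad <- cl[cohort$group == "AD"]
  structure(list(method_label = eq$method_label,
                 yc_mean_cl = mean(yc), yc_sd_cl = sd(yc),
                 ad_mean_cl = mean(ad), r_squared = eq$r_squared),
            class = "calibration_qc")
}

#' Serialize a conversion equation to JSON
#'
#' Writes `{method_label, slope, intercept, r_squared, n_fit, anchors,
#' quality_flag}` with six significant digits for human readers plus a
#' `binary` block of C99 hex-float strings carrying the exact double
#' representation, so read/write round-trips are bit-exact.
#'
#' @param eq A `conversion_equation`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_equation <- function(eq, path) {
  stopifnot(inherits(eq, "conversion_equation"))
  out <- list(method_label = eq$method_label,
              slope = signif(eq$slope, 6),
              intercept = signif(eq$intercept, 6),
              r_squared = signif(eq$r_squared, 6),
              n_fit = eq$n_fit,
              anchors = list(mu_yc = eq$anchors$mu_yc,
                             mu_ad = eq$anchors$mu_ad),
              quality_flag = eq$quality_flag,
              binary = list(slope = sprintf("%a", eq$slope),
                            intercept = sprintf("%a", eq$intercept),
                            r_squared = sprintf("%a", eq$r_squared)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a conversion equation from JSON
#'
#' @param path JSON path written by [write_equation()].
#' @return A `conversion_equation`.
#' @export
read_equation <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pick <- function(field) {
    hex <- x$binary[[field]]
    if (!is.null(hex)) as.numeric(hex) else x[[field]]
  }
  structure(list(method_label = x$method_label, slope = pick("slope"),
                 intercept = pick("intercept"),
                 r_squared = pick("r_squared"),
                 n_fit = as.integer(x$n_fit),
                 anchors = anchor_set(x$anchors$mu_yc, x$anchors$mu_ad),
                 quality_flag = isTRUE(x$quality_flag)),
            class = "conversion_equation")
}
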