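# Cross-sectional and longitudinal cohort statistics: positivity
# classification, variance and mean comparisons with a two-tier significance
# convention, intra-individual variability, accumulation rate, effect size,
# and hypothetical-trial sample size.

#' Amyloid-positivity classification rule
#'
#' @param threshold_cl Threshold in CL.
#' @param positive_if `"greater"` (strict, default) or `"greater_or_equal"`.
#' @return An object of class `classification_rule`.
#' @export
classification_rule <- function(threshold_cl,
                                positive_if = c("greater",
                                                "greater_or_equal")) {
  check_scalar(threshold_cl, "threshold_cl")
  positive_if <- match.arg(positive_if)
  structure(list(threshold_cl = threshold_cl, positive_if = positive_if),
            class = "classification_rule")
}

#' Classify Centiloid values as amyloid positive or negative
#'
#' @param cl Centiloid value(s).
#' @param rule A [classification_rule()].
#' @return Character vector of `"positive"` / `"negative"`.
#' @export
classify <- function(cl, rule) {
  stopifnot(inherits(rule, "classification_rule"))
  pos <- if (rule$positive_if == "greater") cl > rule$threshold_cl
         else cl >= rule$threshold_cl
  ifelse(pos, "positive", "negative")
}

#' Partition longitudinal pairs into stable negatives and accumulators
#'
#' Stable negatives are amyloid negative at both visits; accumulators are
#' positive at either visit (including converters). The two groups partition
#' the input.
#'
#' @param pairs Longitudinal pairs (columns `baseline_cl`, `followup_cl`,
#'   `interval`).
#' @param rule A [classification_rule()].
#' @return List of class `longitudinal_groups` with data frames
#'   `stable_negative` and `accumulator`.
#' @export
longitudinal_groups <- function(pairs, rule) {
  pairs <- as_pairs(pairs)
  neg_both <- classify(pairs$baseline_cl, rule) == "negative" &
    classify(pairs$followup_cl, rule) == "negative"
  structure(list(stable_negative = pairs[neg_both, , drop = FALSE],
                 accumulator = pairs[!neg_both, , drop = FALSE]),
            class = "longitudinal_groups")
}

#' Group mean and sample standard deviation
#'
#' @param values Numeric vector, n >= 2.
#' @return Named list `mean`, `sd` (n - 1 denominator).
#' @export
group_summary <- function(values) {
  if (length(values) < 2) {
    stop_input("group summary needs at least 2 values (got %d)",
               length(values))
  }
  list(mean = mean(values), sd = sd(values))
}

#' Map a p-value to the two-tier significance convention
#'
#' `"overall"` for p < 0.0005 (survives the Bonferroni convention of 100
#' comparisons at family-wise 0.05), `"tentative"` for p < 0.05, `"ns"`
#' otherwise. Both cuts are strict.
#'
#' @param p P-value(s) in \[0, 1\].
#' @return Character vector of `"overall"`, `"tentative"`, `"ns"`.
#' @export
significance_tier <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_input("p-values must lie in [0, 1]")
  }
  ifelse(p < 0.0005, "overall", ifelse(p < 0.05, "tentative", "ns"))
}

#' Bonferroni-corrected significance level
#'
#' @param n_comparisons Number of comparisons in the family (the reporting
#'   convention rounds up to 100 for a family-wise 0.05, giving 0.0005).
#' @param alpha Family-wise error rate (default 0.05).
#' @return `alpha / n_comparisons`.
#' @export
bonferroni_alpha <- function(n_comparisons = 100, alpha = 0.05) {
  check_scalar(n_comparisons, "n_comparisons", lower = 1, integer = TRUE)
  check_scalar(alpha, "alpha", lower = 0, upper = 1, strict = TRUE)
  alpha / n_comparisons
}

comparison_result <- function(statistic, p_value, test, ...) {
  structure(list(statistic = statistic, p_value = p_value,
                 tier = significance_tier(p_value), test = test, ...),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g [%s]\n", x$test, x$statistic,
              x$p_value, x$tier))
  invisible(x)
}

#' F-test comparing the variances of two measurements
#'
#' Two-sided F-test of equality of variances, `F = var(a) / var(b)` against
#' `F(n_a - 1, n_b - 1)`. When `paired = TRUE` the samples come from the same
#' subjects; the plain F-statistic is still reported for fidelity to the
#' classical analysis, alongside the Pitman-Morgan correlation-adjusted test
#' (`pm_statistic`, `pm_p_value`), which is the statistically appropriate
#' paired-variance comparison.
#'
#' @param a,b Numeric samples (each n >= 2; equal length when paired).
#' @param paired Are the samples paired by subject?
#' @return A `comparison_result` with fields `statistic` (F), `p_value`,
#'   `tier`, `test = "variance_F"`, `df`, and when paired also
#'   `pm_statistic`, `pm_p_value`.
#' @export
variance_f_test <- function(a, b, paired = FALSE) {
  if (length(a) < 2 || length(b) < 2) {
    stop_input("variance F-test needs n >= 2 in each sample")
  }
  va <- var(a); vb <- var(b)
  if (vb == 0) stop_input("degenerate F-test: zero variance in denominator")
  f <- va / vb
  d1 <- length(a) - 1L
  d2 <- length(b) - 1L
  p <- 2 * min(pf(f, d1, d2), 1 - pf(f, d1, d2))
  p <- min(p, 1)
  extra <- list(df = c(d1, d2))
  if (paired) {
    if (length(a) != length(b)) {
      stop_input("paired variance comparison needs equal-length samples")
    }
    n <- length(a)
    if (n < 3) stop_input("Pitman-Morgan test needs n >= 3 pairs")
    r <- cor(a, b)
    tstat <- (f - 1) * sqrt(n - 2) / (2 * sqrt(f * (1 - r^2)))
    extra$pm_statistic <- tstat
    extra$pm_p_value <- 2 * pt(-abs(tstat), n - 2)
  }
  do.call(comparison_result,
          c(list(statistic = f, p_value = p, test = "variance_F"), extra))
}

#' Paired t-test on two measurements of the same subjects
#'
#' Standard paired t on the differences, two-sided. Zero-variance differences
#' are handled explicitly: all-zero differences give `t = 0, p = 1`; constant
#' nonzero differences give an infinite t with `p = 0` and
#' `degenerate = TRUE`.
#'
#' @param a,b Equal-length numeric samples, n >= 2.
#' @return A `comparison_result` with `test = "paired_t"` and `df`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    stop_input("paired t-test needs equal-length samples with n >= 2")
  }
  d <- a - b
  n <- length(d)
  s <- sd(d)
  if (s == 0) {
    if (mean(d) == 0) {
      return(comparison_result(0, 1, "paired_t", df = n - 1L,
                               degenerate = TRUE))
    }
    return(comparison_result(sign(mean(d)) * Inf, 0, "paired_t",
                             df = n - 1L, degenerate = TRUE))
  }
  tstat <- mean(d) / (s / sqrt(n))
  comparison_result(tstat, 2 * pt(-abs(tstat), n - 1), "paired_t",
                    df = n - 1L, degenerate = FALSE)
}

#' Intra-individual variability of longitudinal measurements
#'
#' Sample SD of the annualized rate of change among stable amyloid-negative
#' subjects, who are assumed to have minimal true change; this SD is a proxy
#' for longitudinal measurement noise in CL/yr.
#'
#' @param stable Longitudinal pairs of stable-negative subjects (n >= 2).
#' @return SD of the annualized change, in CL/yr.
#' @export
intra_individual_sd <- function(stable) {
  stable <- as_pairs(stable)
  if (nrow(stable) < 2) {
    stop_input("intra-individual variability needs >= 2 stable pairs (got %d)",
               nrow(stable))
  }
  sd(annualized_rate(stable))
}

#' Mean annualized accumulation rate
#'
#' @param accumulators Longitudinal pairs of amyloid accumulators (n >= 1).
#' @return Mean annualized rate of change, CL/yr.
#' @export
mean_annual_rate <- function(accumulators) {
  accumulators <- as_pairs(accumulators)
  if (nrow(accumulators) < 1) {
    stop_input("mean annual rate needs at least one accumulator pair")
  }
  mean(annualized_rate(accumulators))
}

#' Longitudinal effect size
#'
#' Ratio of the mean annualized accumulation rate to the intra-individual
#' variability; both in CL/yr, so the ratio is unitless and indexes the
#' statistical power of a method for detecting longitudinal change.
#'
#' @param rate Mean annualized rate, CL/yr.
#' @param intra_sd Intra-individual variability, CL/yr, > 0.
#' @return `rate / intra_sd`.
#' @export
effect_size <- function(rate, intra_sd) {
  check_scalar(rate, "rate")
  check_scalar(intra_sd, "intra_sd")
  if (intra_sd <= 0) stop_input("'intra_sd' must be > 0 (got %g)", intra_sd)
  rate / intra_sd
}

#' Hypothetical-trial design parameters
#'
#' @param reduction Fractional treatment reduction of the accumulation rate
#'   (default 0.5, i.e. 50%).
#' @param power Target power (default 0.8).
#' @param alpha Two-tailed type-I error (default 0.05).
#' @param duration Trial duration in years (default 1).
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(reduction = 0.5, power = 0.8, alpha = 0.05,
                         duration = 1) {
  check_scalar(reduction, "reduction", lower = 0, upper = 1, strict = FALSE)
  if (reduction <= 0) stop_input("'reduction' must be in (0, 1]")
  check_scalar(power, "power", lower = 0, upper = 1, strict = TRUE)
  check_scalar(alpha, "alpha", lower = 0, upper = 1, strict = TRUE)
  check_scalar(duration, "duration", lower = 0, strict = TRUE)
  structure(list(reduction = reduction, power = power, alpha = alpha,
                 duration = duration), class = "trial_design")
}

#' Participants per arm for a rate-reduction trial
#'
#' Normal-approximation two-sample difference-of-means formula:
#' `n = ceil(2 (z_{1-alpha/2} + z_power)^2 sigma^2 / delta^2)` with treatment
#' effect `delta = reduction * rate * duration` and per-subject change SD
#' `sigma = intra_sd * duration` (the annualized intra-individual variability
#' scaled to the trial duration).
#'
#' @param rate Untreated mean annualized accumulation rate, CL/yr, > 0.
#' @param intra_sd Annualized intra-individual variability, CL/yr, > 0.
#' @param design A [trial_design()].
#' @return Integer participants per arm.
#' @export
trial_sample_size <- function(rate, intra_sd, design = trial_design()) {
  stopifnot(inherits(design, "trial_design"))
  check_scalar(rate, "rate")
  check_scalar(intra_sd, "intra_sd")
  if (rate <= 0) stop_input("'rate' must be > 0 (got %g)", rate)
  if (intra_sd <= 0) stop_input("'intra_sd' must be > 0 (got %g)", intra_sd)
  delta <- design$reduction * rate * design$duration
  sigma <- intra_sd * design$duration
  z <- qnorm(1 - design$alpha / 2) + qnorm(design$power)
  as.integer(ceiling(2 * z^2 * sigma^2 / delta^2))
}
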