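# End-to-end orchestration: simulate -> calibrate -> thresholds -> statistics,
# with typed table readers, a JSON results bundle, delimited report tables and
# a checksummed file manifest.

#' Pipeline run configuration
#'
#' Bundles everything a full synthetic run needs. Each method entry describes
#' how that quantification variant's native values relate to the standard
#' SUVr (`slope`, `intercept`, native-scale `noise_sd`), its per-visit
#' measurement noise in CL (`cl_noise_sd`), and an optional empirical
#' native-scale positivity cutoff (`native_threshold`).
#'
#' @param seed Master integer seed; every stage derives its stream from it.
#' @param anchors An [anchor_set()].
#' @param methods List of method entries, each a list with `label`, `slope`,
#'   `intercept`, `noise_sd`, `cl_noise_sd` and optionally
#'   `native_threshold`. Labels must be unique.
#' @param calibration List with `n_yc`, `n_ad`, `yc_sd`, `ad_sd` for the
#'   synthetic calibration cohort (group means come from `anchors`).
#' @param longitudinal A [longitudinal_sim_params()] object; its
#'   `measurement_noise_sd` is ignored (per-method `cl_noise_sd` is used on a
#'   shared noise-free truth so methods stay comparable subject-by-subject).
#' @param cross_sectional List with `n`, `mixture` for the cross-sectional
#'   cohort.
#' @param classification A [classification_rule()] used to split the
#'   longitudinal cohort (default threshold 10.7 CL, strict).
#' @param thresholds List of threshold options (`span`, `n_boot`, `ci_level`,
#'   `percentile`, `grid_min`, `grid_max`).
#' @param trial A [trial_design()].
#' @param n_comparisons Comparison-family size used for the corrected alpha
#'   convention (default 100, giving 0.0005).
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       anchors = anchor_set(1.05, 2.05),
                       methods = default_methods(),
                       calibration = list(n_yc = 18, n_ad = 18,
                                          yc_sd = 0.05, ad_sd = 0.20),
                       longitudinal = longitudinal_sim_params(seed = seed),
                       cross_sectional = list(n = 590,
                                              mixture = list(
                                                weights = c(0.75, 0.25),
                                                means = c(0, 60),
                                                sds = c(6, 25))),
                       classification = classification_rule(10.7),
                       thresholds = list(span = 0.75, n_boot = 200,
                                         ci_level = 0.95, percentile = 0.95,
                                         grid_min = NULL, grid_max = NULL),
                       trial = trial_design(),
                       n_comparisons = 100) {
  check_scalar(seed, "seed", integer = TRUE)
  stopifnot(inherits(anchors, "anchor_set"),
            inherits(longitudinal, "longitudinal_sim_params"),
            inherits(classification, "classification_rule"),
            inherits(trial, "trial_design"))
  labels <- vapply(methods, function(m) m$label, character(1))
  if (anyDuplicated(labels)) stop_input("method labels must be unique")
  for (m in methods) {
    for (f in c("slope", "intercept", "noise_sd", "cl_noise_sd")) {
      if (is.null(m[[f]])) stop_input("method '%s' lacks field '%s'",
                                      m$label, f)
    }
    if (m$slope == 0) stop_input("method '%s' has zero slope", m$label)
  }
  structure(list(seed = as.integer(seed), anchors = anchors,
                 methods = methods, calibration = calibration,
                 longitudinal = longitudinal,
                 cross_sectional = cross_sectional,
                 classification = classification, thresholds = thresholds,
                 trial = trial, n_comparisons = n_comparisons),
            class = "run_config")
}

#' Default demo method set
#'
#' Four representative quantification variants whose native scales and noise
#' levels emulate windowed SUVr with and without partial-volume correction,
#' binding potential with partial-volume correction, and brainstem-referenced
#' SUVr.
#'
#' @return List of method entries for [run_config()].
#' @export
default_methods <- function() {
  list(
    list(label = "CL_3060_SUVr", slope = 1.05, intercept = -0.02,
         noise_sd = 0.06, cl_noise_sd = 3.0, native_threshold = NULL),
    list(label = "CL_3060_SUVr_RSF", slope = 1.25, intercept = -0.18,
         noise_sd = 0.045, cl_noise_sd = 2.4, native_threshold = 1.42),
    list(label = "CL_3060_BP_RSF", slope = 1.30, intercept = -1.35,
         noise_sd = 0.040, cl_noise_sd = 2.1, native_threshold = 0.18),
    list(label = "CL_3060_SUVr_BS", slope = 0.85, intercept = 0.12,
         noise_sd = 0.080, cl_noise_sd = 3.6, native_threshold = NULL))
}

# Stage seeds derived from the master seed; offsets keep every derived seed a
# valid 32-bit integer for small master seeds.
stage_seed <- function(seed, stage, i = 0L) {
  (as.integer(seed) * 97L + stage * 1009L + i * 131L) %% .Machine$integer.max
}

#' Run the full synthetic analysis pipeline
#'
#' Generates a shared calibration cohort (standard SUVr per subject) and a
#' shared noise-free longitudinal and cross-sectional truth, then per method:
#' adds method-specific noise, fits the level-2 conversion, produces the
#' calibration QC row, the three positivity thresholds, cross-sectional group
#' summaries and the longitudinal statistics (intra-individual variability,
#' accumulation rate, effect size, trial sample size, paired test of
#' longitudinal change). Methods are compared pairwise (paired variance F and
#' paired t on the cross-sectional values). Deterministic given the seed; a
#' method whose stage fails is reported with an `error` field without
#' aborting the others.
#'
#' @param config A [run_config()].
#' @return An object of class `run_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  anchors <- config$anchors
  cal <- config$calibration
  # shared standard-scale calibration cohort
  std_cohort <- gen_calibration_cohort(cohort_params(
    n_yc = cal$n_yc, n_ad = cal$n_ad,
    yc_mean_std_suvr = anchors$mu_yc, ad_mean_std_suvr = anchors$mu_ad,
    yc_sd = cal$yc_sd, ad_sd = cal$ad_sd,
    method_slope = 1, method_intercept = 0, method_noise_sd = 0,
    seed = stage_seed(config$seed, 1L)))
  # shared noise-free longitudinal truth
  lp <- config$longitudinal
  lp$measurement_noise_sd <- 0
  lp$seed <- stage_seed(config$seed, 2L)
  lcohort <- gen_longitudinal_cohort(lp)
  # shared cross-sectional truth
  xs <- gen_cross_sectional_cohort(n = config$cross_sectional$n,
                                   mixture = config$cross_sectional$mixture,
                                   measurement_noise_sd = 0,
                                   seed = stage_seed(config$seed, 3L))
  rule <- config$classification
  tcfg <- config$thresholds
  per_method <- list()
  xs_cl <- list()
  for (i in seq_along(config$methods)) {
    m <- config$methods[[i]]
    res <- tryCatch({
      mseed <- stage_seed(config$seed, 10L, i)
      cohort <- std_cohort
      cohort$method_value <- with_seed(mseed,
        m$slope * cohort$standard_suvr + m$intercept +
          rnorm(nrow(cohort), 0, m$noise_sd))
      eq <- fit_level2(cohort, anchors, m$label)
      qc <- calibration_report(eq, cohort)
      yc_cl <- apply_equation(eq, cohort$method_value[cohort$group == "YC"])
      # per-method observed longitudinal values on the shared truth
      nlong <- nrow(lcohort)
      noise <- with_seed(stage_seed(config$seed, 20L, i),
                         rnorm(2 * nlong, 0, m$cl_noise_sd))
      pairs <- longitudinal_pairs(lcohort$subject,
                                  lcohort$baseline_true + noise[1:nlong],
                                  lcohort$followup_true +
                                    noise[(nlong + 1):(2 * nlong)],
                                  lcohort$interval)
      thr <- build_threshold_set(eq, yc_cl, pairs, utils::modifyList(
        tcfg, list(native_threshold = m$native_threshold,
                   seed = stage_seed(config$seed, 30L, i))))
      # cross-sectional observed values
      xcl <- xs$true_cl + with_seed(stage_seed(config$seed, 40L, i),
                                    rnorm(nrow(xs), 0, m$cl_noise_sd))
      xstatus <- classify(xcl, rule)
      xneg <- xcl[xstatus == "negative"]
      xpos <- xcl[xstatus == "positive"]
      cross <- list(n = length(xcl),
                    n_negative = length(xneg), n_positive = length(xpos),
                    a_neg_mean = if (length(xneg) >= 2) mean(xneg) else NA_real_,
                    a_neg_sd = if (length(xneg) >= 2) sd(xneg) else NA_real_,
                    a_pos_mean = if (length(xpos) >= 2) mean(xpos) else NA_real_,
                    a_pos_sd = if (length(xpos) >= 2) sd(xpos) else NA_real_)
      groups <- longitudinal_groups(pairs, rule)
      long <- list(n_stable = nrow(groups$stable_negative),
                   n_accumulator = nrow(groups$accumulator))
      if (long$n_stable >= 2) {
        long$intra_sd <- intra_individual_sd(groups$stable_negative)
      } else {
        long$intra_sd <- NA_real_
      }
      if (long$n_accumulator >= 2) {
        long$rate <- mean_annual_rate(groups$accumulator)
        tt <- paired_t_test(groups$accumulator$followup_cl,
                            groups$accumulator$baseline_cl)
        long$change_t <- tt$statistic
        long$change_p <- tt$p_value
        long$change_tier <- tt$tier
      } else {
        long$rate <- NA_real_
        long$change_t <- NA_real_
        long$change_p <- NA_real_
        long$change_tier <- NA_character_
      }
      if (is.finite(long$intra_sd) && is.finite(long$rate) &&
          long$intra_sd > 0 && long$rate > 0) {
        long$effect_size <- effect_size(long$rate, long$intra_sd)
        long$n_per_arm <- trial_sample_size(long$rate, long$intra_sd,
                                            config$trial)
      } else {
        long$effect_size <- NA_real_
        long$n_per_arm <- NA_integer_
      }
      xs_cl[[m$label]] <- xcl
      list(label = m$label, equation = eq, calibration = qc,
           thresholds = thr, cross_sectional = cross, longitudinal = long)
    }, error = function(e) {
      list(label = m$label, error = conditionMessage(e))
    })
    per_method[[m$label]] <- res
  }
  # pairwise method comparisons on the cross-sectional values
  labs <- names(xs_cl)
  comparisons <- NULL
  n_tests <- 0L
  if (length(labs) >= 2) {
    combs <- utils::combn(labs, 2)
    rows <- vector("list", ncol(combs))
    for (j in seq_len(ncol(combs))) {
      a <- xs_cl[[combs[1, j]]]
      b <- xs_cl[[combs[2, j]]]
      fv <- variance_f_test(a, b, paired = TRUE)
      tv <- paired_t_test(a, b)
      n_tests <- n_tests + 2L
      rows[[j]] <- data.frame(method_a = combs[1, j], method_b = combs[2, j],
                              f_statistic = fv$statistic, f_p = fv$p_value,
                              f_tier = fv$tier,
                              pm_statistic = fv$pm_statistic,
                              pm_p = fv$pm_p_value,
                              t_statistic = tv$statistic, t_p = tv$p_value,
                              t_tier = tv$tier,
                              stringsAsFactors = FALSE)
    }
    comparisons <- do.call(rbind, rows)
  }
  structure(list(
    provenance = list(seed = config$seed,
                      config_hash = config_hash(config),
                      package_version = as.character(
                        utils::packageVersion("centiloidr")),
                      n_tests_performed = n_tests,
                      comparison_family_size = config$n_comparisons,
                      corrected_alpha = bonferroni_alpha(config$n_comparisons)),
    methods = per_method,
    comparisons = comparisons),
    class = "run_report")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  ser <- rapply(unclass(config), function(x) {
    if (is.function(x)) "<function>" else x
  }, how = "replace")
  jsonlite::write_json(ser, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Centiloid pipeline report: %d methods, seed %d\n",
              length(x$methods), x$provenance$seed))
  for (m in x$methods) {
    if (!is.null(m$error)) {
      cat(sprintf("  %s: FAILED (%s)\n", m$label, m$error))
    } else {
      cat(sprintf("  %s: YC %.1f +/- %.1f CL, AD %.1f CL, RW %s CL, N/arm %s\n",
                  m$label, m$calibration$yc_mean_cl, m$calibration$yc_sd_cl,
                  m$calibration$ad_mean_cl,
                  if (is.na(m$thresholds$rw_cl)) "-" else m$thresholds$rw_cl,
                  if (is.na(m$longitudinal$n_per_arm)) "-"
                  else m$longitudinal$n_per_arm))
    }
  }
  invisible(x)
}

#' Read and validate a cohort table
#'
#' Reads comma-separated text with a header row. `type = "calibration"`
#' requires columns `subject`, `group`, `standard_suvr`, `method_value`;
#' `type = "longitudinal"` requires `subject`, `baseline_cl`, `followup_cl`,
#' `interval`. Missing columns raise a schema error naming them; non-numeric
#' cells and non-positive intervals are rejected with their file line
#' numbers.
#'
#' @param path CSV path.
#' @param type `"calibration"` or `"longitudinal"`.
#' @return A validated data frame (for longitudinal input, a
#'   [longitudinal_pairs()] table).
#' @export
read_cohort_table <- function(path, type = c("calibration", "longitudinal")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop_input("file not found: %s", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- switch(type,
    calibration = c("subject", "group", "standard_suvr", "method_value"),
    longitudinal = c("subject", "baseline_cl", "followup_cl", "interval"))
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop_input("'%s' is missing required column(s): %s", path,
               paste(missing, collapse = ", "))
  }
  num_cols <- setdiff(required, c("subject", "group"))
  for (cn in num_cols) {
    vals <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(is.na(vals) & nzchar(trimws(raw[[cn]])))
    nas <- which(!nzchar(trimws(raw[[cn]])))
    bad <- sort(c(bad, nas))
    if (length(bad)) {
      stop_input("non-numeric value(s) in column '%s' at line(s) %s of %s",
                 cn, paste(bad + 1L, collapse = ", "), path)
    }
    raw[[cn]] <- vals
  }
  if (type == "longitudinal") {
    bad <- which(raw$interval <= 0)
    if (length(bad)) {
      stop_input("non-positive interval(s) at line(s) %s of %s",
                 paste(bad + 1L, collapse = ", "), path)
    }
    return(longitudinal_pairs(raw$subject, raw$baseline_cl, raw$followup_cl,
                              raw$interval))
  }
  raw[required]
}

#' Read a TAC table
#'
#' Expects columns `frame_mid_time_min`, `frame_duration_min`, then one
#' activity column per region.
#'
#' @param path CSV path.
#' @return Named list of [tac()] objects, one per region column.
#' @export
read_tac_table <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_mid_time_min", "frame_duration_min")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop_input("'%s' is missing required column(s): %s", path,
               paste(missing, collapse = ", "))
  }
  regions <- setdiff(names(tab), need)
  if (!length(regions)) stop_input("'%s' has no activity columns", path)
  stats::setNames(lapply(regions, function(r) {
    tac(tab$frame_mid_time_min, tab$frame_duration_min, tab[[r]])
  }), regions)
}

#' Read a regional mixing matrix
#'
#' Square comma-separated matrix whose header row names the regions.
#'
#' @param path CSV path.
#' @return Numeric matrix with row and column names.
#' @export
read_mixing_matrix <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  M <- as.matrix(tab)
  if (nrow(M) != ncol(M)) {
    stop_input("mixing matrix in '%s' is not square (%d x %d)", path,
               nrow(M), ncol(M))
  }
  storage.mode(M) <- "double"
  rownames(M) <- colnames(M)
  M
}

report_table <- function(report, rows, extract) {
  labs <- names(report$methods)
  out <- data.frame(quantity = rows, stringsAsFactors = FALSE)
  for (lab in labs) {
    m <- report$methods[[lab]]
    out[[lab]] <- if (!is.null(m$error)) rep(NA_real_, length(rows)) else
      vapply(rows, function(r) {
        v <- extract(m, r)
        if (is.null(v) || length(v) != 1 || is.na(v)) NA_real_ else as.numeric(v)
      }, numeric(1))
  }
  out
}

#' Write the report bundle to disk
#'
#' Writes a JSON results bundle, calibration / cross-sectional / longitudinal
#' summary tables (rows = quantities, one column per method), a rate-curve
#' table per method, the pairwise comparison table, and a manifest listing
#' every written file with its MD5 checksum. Missing values are empty cells
#' in the delimited output and nulls in the JSON — never sentinel numbers.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if absent).
#' @return Data frame manifest (`file`, `md5`), invisibly written as
#'   `manifest.csv` too.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop_input("cannot create output directory '%s'", dir)
  files <- character(0)
  bundle_path <- file.path(dir, "report.json")
  bundle <- rapply(unclass(report), function(x) x, how = "replace")
  jsonlite::write_json(bundle, bundle_path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", force = TRUE)
  files <- c(files, bundle_path)

  calib <- report_table(report,
    c("yc_mean_cl", "yc_sd_cl", "ad_mean_cl", "r_squared",
      "specificity_cl"),
    function(m, r) {
      if (r == "specificity_cl") m$thresholds$specificity_cl
      else m$calibration[[r]]
    })
  cross <- report_table(report,
    c("a_neg_mean", "a_neg_sd", "a_pos_mean", "a_pos_sd", "rw_cl",
      "specificity_cl", "empirical_cl"),
    function(m, r) {
      if (r %in% c("rw_cl", "specificity_cl", "empirical_cl")) {
        m$thresholds[[r]]
      } else {
        m$cross_sectional[[r]]
      }
    })
  long <- report_table(report,
    c("intra_sd", "rate", "effect_size", "n_per_arm", "change_p"),
    function(m, r) m$longitudinal[[r]])
  for (nm in c("calibration", "cross_sectional", "longitudinal")) {
    tab <- switch(nm, calibration = calib, cross_sectional = cross,
                  longitudinal = long)
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(tab, p, row.names = FALSE, na = "")
    files <- c(files, p)
  }
  for (lab in names(report$methods)) {
    m <- report$methods[[lab]]
    if (is.null(m$error) && !is.null(m$thresholds$curve)) {
      p <- file.path(dir, paste0("curve_", lab, ".csv"))
      write.csv(curve_table(m$thresholds$curve), p, row.names = FALSE,
                na = "")
      files <- c(files, p)
    }
  }
  if (!is.null(report$comparisons)) {
    p <- file.path(dir, "comparisons.csv")
    write.csv(report$comparisons, p, row.names = FALSE, na = "")
    files <- c(files, p)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read back the JSON report bundle
#'
#' @param dir Directory written by [write_report()].
#' @return The deserialized bundle (nested lists).
#' @export
read_report <- function(dir) {
  path <- file.path(dir, "report.json")
  if (!file.exists(path)) stop_input("no report.json under '%s'", dir)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
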