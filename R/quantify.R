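# Native amyloid-burden quantification primitives: windowed SUVr, Logan
# reference-tissue graphical analysis, mixing-matrix partial-volume
# correction, and the mean cortical index.

#' Time-activity curve
#'
#' @param frame_mid_times Strictly increasing frame mid-times (minutes
#'   post-injection).
#' @param frame_durations Frame durations (minutes), > 0.
#' @param activity Regional tracer concentration per frame (any consistent
#'   unit; SUVr and binding potential are unit-free ratios).
#' @return An object of class `tac`.
#' @export
tac <- function(frame_mid_times, frame_durations, activity) {
  frame_mid_times <- as.numeric(frame_mid_times)
  frame_durations <- as.numeric(frame_durations)
  activity <- as.numeric(activity)
  n <- length(frame_mid_times)
  if (length(frame_durations) != n || length(activity) != n) {
    stop_input("TAC vectors must have equal length")
  }
  if (n < 1 || any(diff(frame_mid_times) <= 0)) {
    stop_input("'frame_mid_times' must be strictly increasing")
  }
  if (any(frame_durations <= 0)) stop_input("'frame_durations' must be > 0")
  if (any(!is.finite(activity))) stop_input("'activity' must be finite")
  structure(list(frame_mid_times = frame_mid_times,
                 frame_durations = frame_durations,
                 activity = activity),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("Time-activity curve: %d frames, %.1f-%.1f min\n",
              length(x$frame_mid_times), min(x$frame_mid_times),
              max(x$frame_mid_times)))
  invisible(x)
}

#' Post-injection time window
#'
#' @param start,end Window bounds in minutes post-injection;
#'   `0 <= start < end`.
#' @return An object of class `time_window`.
#' @export
time_window <- function(start, end) {
  check_scalar(start, "start", lower = 0)
  check_scalar(end, "end")
  if (start >= end) stop_input("window start (%g) must be < end (%g)",
                               start, end)
  structure(list(start = start, end = end), class = "time_window")
}

#' Quantification method descriptor
#'
#' Identifies one variant of the amyloid quantification pipeline: the metric
#' (windowed SUVr or Logan binding potential), whether partial-volume
#' correction is applied, the reference region, and the post-injection window.
#'
#' @param label Unique method label (e.g. `"CL_3060_SUVr_RSF"`).
#' @param metric `"SUVr"` or `"BP"` (BP requires dynamic TAC input).
#' @param pvc Logical; apply regional mixing (partial-volume) correction.
#' @param reference Reference region: `"cerebellar_cortex"` (default),
#'   `"brainstem"`, or `"whole_cerebellum"`.
#' @param window A [time_window()]; default 30-60 min.
#' @return An object of class `method_spec`.
#' @export
method_spec <- function(label, metric = c("SUVr", "BP"), pvc = FALSE,
                        reference = c("cerebellar_cortex", "brainstem",
                                      "whole_cerebellum"),
                        window = time_window(30, 60)) {
  metric <- match.arg(metric)
  reference <- match.arg(reference)
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop_input("'label' must be a non-empty string")
  }
  if (!inherits(window, "time_window")) {
    stop_input("'window' must be a time_window")
  }
  structure(list(label = label, metric = metric, pvc = isTRUE(pvc),
                 reference = reference, window = window),
            class = "method_spec")
}

#' Regional metric values
#'
#' @param names Unique region names.
#' @param values Finite metric values, one per region.
#' @param metric Metric the values are on (`"SUVr"`, `"BP"`, or
#'   `"activity"`).
#' @return An object of class `regional_values`.
#' @export
regional_values <- function(names, values, metric = "activity") {
  names <- as.character(names)
  values <- as.numeric(values)
  if (length(names) != length(values)) {
    stop_input("'names' and 'values' must have equal length")
  }
  if (anyDuplicated(names)) stop_input("region names must be unique")
  if (any(!is.finite(values))) stop_input("regional values must be finite")
  structure(list(names = names, values = values, metric = metric),
            class = "regional_values")
}

window_index <- function(tac, window) {
  which(tac$frame_mid_times >= window$start & tac$frame_mid_times <= window$end)
}

#' Duration-weighted mean activity over a time window
#'
#' Frames belong to the window when their mid-time lies in the closed interval
#' `[start, end]`; the mean is weighted by frame duration, reproducing the
#' value of a duration-weighted summed image over the window.
#'
#' @param tac A [tac()].
#' @param window A [time_window()].
#' @return Mean activity over the window.
#' @export
window_mean <- function(tac, window) {
  stopifnot(inherits(tac, "tac"), inherits(window, "time_window"))
  idx <- window_index(tac, window)
  if (!length(idx)) {
    stop_input("no frame mid-times fall in window [%g, %g] min",
               window$start, window$end)
  }
  sum(tac$activity[idx] * tac$frame_durations[idx]) /
    sum(tac$frame_durations[idx])
}

same_frame_grid <- function(a, b) {
  length(a$frame_mid_times) == length(b$frame_mid_times) &&
    isTRUE(all.equal(a$frame_mid_times, b$frame_mid_times)) &&
    isTRUE(all.equal(a$frame_durations, b$frame_durations))
}

#' Standard uptake value ratio over a window
#'
#' @param target,reference [tac()] objects on the same frame grid.
#' @param window A [time_window()].
#' @return `window_mean(target) / window_mean(reference)`.
#' @export
suvr <- function(target, reference, window) {
  stopifnot(inherits(target, "tac"), inherits(reference, "tac"))
  if (!same_frame_grid(target, reference)) {
    stop_input("target and reference TACs must share the same frame grid")
  }
  ref_mean <- window_mean(reference, window)
  if (ref_mean <= 0) {
    stop_input("reference window mean is %g; SUVr requires a positive reference",
               ref_mean)
  }
  window_mean(target, window) / ref_mean
}

# Running integral from time 0 at the frame mid-times: trapezoid between
# mid-times, with the leading segment from t = 0 to the first mid-time treated
# as a triangle rising from zero activity.
cum_integral <- function(t, y) {
  inc <- c(0.5 * t[1] * y[1],
           diff(t) * (head(y, -1) + tail(y, -1)) / 2)
  cumsum(inc)
}

#' Logan reference-tissue graphical analysis
#'
#' Estimates the non-displaceable binding potential from target and
#' reference-region TACs. For frames with mid-time at or after `t_star`, the
#' running integrals of both curves (trapezoid from time 0) are normalized by
#' the instantaneous target activity and regressed:
#' `int(target)/target ~ int(reference)/target`; the asymptotic slope is the
#' distribution volume ratio and `BP_ND = slope - 1`. The reference-efflux
#' (k2') correction term is omitted; the estimate is asymptotically unbiased
#' once the target-to-reference ratio is in pseudo-equilibrium.
#'
#' @param target,reference [tac()] objects on the same frame grid.
#' @param t_star Start of the linear segment in minutes (default 30).
#' @return Estimated `BP_ND`.
#' @export
logan_bp <- function(target, reference, t_star = 30) {
  stopifnot(inherits(target, "tac"), inherits(reference, "tac"))
  if (!same_frame_grid(target, reference)) {
    stop_input("target and reference TACs must share the same frame grid")
  }
  t <- target$frame_mid_times
  keep <- which(t >= t_star)
  if (length(keep) < 3) {
    stop_input("Logan fit needs >= 3 frames with mid-time >= t_star = %g min (found %d)",
               t_star, length(keep))
  }
  ct <- target$activity
  if (any(ct[keep] <= 0)) {
    stop_input("target activity must be positive on all frames used in the Logan fit")
  }
  int_t <- cum_integral(t, ct)
  int_r <- cum_integral(t, reference$activity)
  x <- int_r[keep] / ct[keep]
  y <- int_t[keep] / ct[keep]
  if (var(x) <= 0) stop_input("degenerate Logan regressor (constant x)")
  slope <- cov(x, y) / var(x)
  slope - 1
}

#' Mixing-matrix (GTM-style) partial-volume correction
#'
#' Treats observed regional means as a row-stochastic mixing of the true
#' means (`observed = M true`) — the regional-spread-function picture of
#' scanner blur collapsed to region level — and inverts the mixing by a
#' linear solve.
#'
#' @param observed Observed regional means: a numeric vector or a
#'   [regional_values()] object.
#' @param mixing_matrix Square matrix, rows summing to 1 within 1e-6,
#'   condition number below 1e8.
#' @return Corrected means, same container type as `observed`.
#' @export
pvc_correct <- function(observed, mixing_matrix) {
  vals <- if (inherits(observed, "regional_values")) observed$values
          else as.numeric(observed)
  M <- as.matrix(mixing_matrix)
  k <- length(vals)
  if (!all(dim(M) == k)) {
    stop_input("mixing matrix must be %d x %d to match the regions", k, k)
  }
  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-6)) {
    stop_input("mixing matrix rows must sum to 1 (max deviation %g)",
               max(abs(rs - 1)))
  }
  cond <- kappa(M, exact = TRUE)
  if (!is.finite(cond) || cond > 1e8) {
    stop_input("mixing matrix is ill-conditioned (condition number %g)", cond)
  }
  corrected <- drop(solve(M, vals))
  if (inherits(observed, "regional_values")) {
    regional_values(observed$names, corrected, observed$metric)
  } else {
    corrected
  }
}

#' Mean cortical index
#'
#' Global amyloid-burden index: (weighted) mean of a regional metric over a
#' selected set of cortical regions (typically frontal, parietal, temporal
#' and precuneus cortex). Unweighted by default.
#'
#' @param regional A [regional_values()] object or named numeric vector.
#' @param region_set Region names to aggregate (default: all regions).
#' @param weights Optional nonnegative weights, one per entry of
#'   `region_set`, not all zero.
#' @return The scalar index.
#' @export
mean_cortical_index <- function(regional, region_set = NULL, weights = NULL) {
  if (inherits(regional, "regional_values")) {
    vals <- stats::setNames(regional$values, regional$names)
  } else {
    vals <- regional
    if (is.null(names(vals))) stop_input("'regional' must carry region names")
  }
  if (is.null(region_set)) region_set <- names(vals)
  missing <- setdiff(region_set, names(vals))
  if (length(missing)) {
    stop_input("unknown region(s): %s", paste(missing, collapse = ", "))
  }
  x <- vals[region_set]
  if (is.null(weights)) return(mean(x))
  weights <- as.numeric(weights)
  if (length(weights) != length(region_set) || any(weights < 0) ||
      sum(weights) <= 0) {
    stop_input("'weights' must be nonnegative, not all zero, one per region")
  }
  sum(x * weights) / sum(weights)
}

#' Mean image intensity within a labelled region
#'
#' @param image Numeric array of voxel intensities.
#' @param labels Integer-valued array of the same dimensions.
#' @param label_id Label value selecting the region.
#' @return Mean intensity over voxels where `labels == label_id`.
#' @export
regional_mean_from_volume <- function(image, labels, label_id) {
  if (!identical(dim(image), dim(labels))) {
    stop_input("image and label volumes must share the same grid")
  }
  sel <- which(labels == label_id)
  if (!length(sel)) stop_input("label %s not present in the label volume",
                               format(label_id))
  mean(image[sel])
}
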