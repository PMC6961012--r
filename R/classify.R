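#' Adjustable classifier parameters
#'
#' The decision tree has three adjustable parameters: the segmentation
#' window size WS (s), the physical-activity threshold PA Th (counts per
#' second, cps) applied to the windowed SMA, and the sensor-orientation
#' threshold SO Th (g) applied to the mean longitudinal gravity
#' component of static windows. Defaults are the settings optimized for
#' healthy elderly wearing the sensor on the upper leg: WS = 2 s,
#' PA Th = 7 cps, SO Th = 0.8 g (0.8 g corresponds to a thigh angle of
#' 36 degrees from the gravity vector, see [orientation_angle()]).
#'
#' One count is defined as 1 g-second of rectified body acceleration
#' summed over the three axes, so the SMA in cps is the window sum
#' divided by the window length in seconds; `count_scale` rescales this
#' to match other hardware conventions.
#'
#' @param window_size WS in seconds (> 0).
#' @param pa_threshold PA Th in cps (> 0).
#' @param so_threshold SO Th in g, in (0, 1].
#' @param orientation_sign +1 if the X axis points toward the hip
#'   (standing gives g_x ~ +1 g), -1 for an inverted sensor.
#' @param count_scale multiplier applied to the SMA (default 1).
#' @param constants a [filter_constants()] object.
#' @return object of class `algorithm_parameters`.
#' @export
algorithm_parameters <- function(window_size = 2, pa_threshold = 7,
                                 so_threshold = 0.8, orientation_sign = 1,
                                 count_scale = 1,
                                 constants = filter_constants()) {
  if (window_size <= 0) stop("window_size must be positive", call. = FALSE)
  if (pa_threshold <= 0) stop("pa_threshold must be positive", call. = FALSE)
  if (so_threshold <= 0 || so_threshold > 1) {
    stop("so_threshold must be in (0, 1] g", call. = FALSE)
  }
  if (!orientation_sign %in% c(-1, 1)) {
    stop("orientation_sign must be +1 or -1", call. = FALSE)
  }
  if (count_scale <= 0) stop("count_scale must be positive", call. = FALSE)
  stopifnot(inherits(constants, "filter_constants"))
  structure(list(window_size = window_size, pa_threshold = pa_threshold,
                 so_threshold = so_threshold,
                 orientation_sign = orientation_sign,
                 count_scale = count_scale,
                 filter_constants = constants),
            class = "algorithm_parameters")
}

#' @export
print.algorithm_parameters <- function(x, ...) {
  cat(sprintf("<algorithm_parameters> WS = %g s, PA Th = %g cps, SO Th = %g g\n",
              x$window_size, x$pa_threshold, x$so_threshold))
  invisible(x)
}

#' Thigh angle corresponding to an orientation threshold
#'
#' The longitudinal gravity projection equals cos(angle between the
#' gravity vector and the thigh axis), so a threshold of 0.8 g separates
#' postures at arccos(0.8) = 36 degrees (truncated).
#'
#' @param so_threshold orientation threshold in g, in (0, 1].
#' @return angle from vertical in degrees.
#' @export
orientation_angle <- function(so_threshold = 0.8) {
  if (any(so_threshold <= 0 | so_threshold > 1)) {
    stop("so_threshold must be in (0, 1]", call. = FALSE)
  }
  acos(so_threshold) * 180 / pi
}

#' Fixed non-overlapping window segmentation
#'
#' Splits `signal_length` samples into consecutive windows of
#' `N = round(window_size * sampling_rate)` samples; the trailing
#' partial window is discarded (SMA and mean gravity are defined only
#' over complete windows).
#'
#' @param signal_length number of samples.
#' @param sampling_rate Hz.
#' @param window_size window size in seconds.
#' @return integer matrix with columns `start`, `end` (1-based,
#'   inclusive), one row per window; attribute `dropped_samples` holds
#'   the discarded tail length.
#' @export
segment_windows <- function(signal_length, sampling_rate, window_size) {
  n_win_samples <- round(window_size * sampling_rate)
  if (n_win_samples < 1) {
    stop("window_size must cover at least one sample", call. = FALSE)
  }
  k <- floor(signal_length / n_win_samples)
  starts <- (seq_len(k) - 1L) * n_win_samples + 1L
  out <- cbind(start = as.integer(starts),
               end = as.integer(starts + n_win_samples - 1L))
  attr(out, "dropped_samples") <- as.integer(signal_length - k * n_win_samples)
  out
}

#' Signal magnitude area of one window, in counts per second
#'
#' SMA of window j is the sum of the rectified body acceleration over
#' all three axes and all samples of the window; dividing by the window
#' length in seconds expresses it in counts per second, independent of
#' the window size.
#'
#' @param ba_window N x 3 matrix of body acceleration in g.
#' @param window_size window length in seconds.
#' @param count_scale count-unit multiplier (default 1).
#' @return SMA in cps (>= 0).
#' @export
compute_sma_cps <- function(ba_window, window_size, count_scale = 1) {
  ba_window <- as.matrix(ba_window)
  if (nrow(ba_window) < 1L) stop("empty window", call. = FALSE)
  if (!all(is.finite(ba_window))) stop("window contains non-finite values",
                                       call. = FALSE)
  sum(abs(ba_window)) / window_size * count_scale
}

#' Mean gravity vector of one window
#'
#' Per-axis arithmetic mean of the gravitational-acceleration component
#' over the samples of a complete window.
#'
#' @param ga_window N x 3 matrix of gravitational acceleration in g.
#' @return numeric vector `(g_x, g_y, g_z)` in g.
#' @export
compute_mean_gravity <- function(ga_window) {
  ga_window <- as.matrix(ga_window)
  if (nrow(ga_window) < 1L) stop("empty window", call. = FALSE)
  if (!all(is.finite(ga_window))) stop("window contains non-finite values",
                                       call. = FALSE)
  stats::setNames(colMeans(ga_window), c("g_x", "g_y", "g_z"))
}

#' Decision-tree classification of windows
#'
#' A window is `dynamic` when its SMA reaches the physical-activity
#' threshold (`sma_cps >= pa_threshold`); otherwise it is static and the
#' longitudinal gravity component decides the posture: `standing` when
#' `orientation_sign * g_x >= so_threshold`, else `sedentary`. Both
#' boundary comparisons are inclusive.
#'
#' @param sma_cps numeric vector of window SMA values in cps.
#' @param ga_x numeric vector of window mean gravity on the X axis in g.
#' @param params an [algorithm_parameters()] object.
#' @return factor of labels with levels [activity_levels()].
#' @export
classify_window <- function(sma_cps, ga_x, params = algorithm_parameters()) {
  stopifnot(inherits(params, "algorithm_parameters"),
            length(sma_cps) == length(ga_x))
  lab <- ifelse(sma_cps >= params$pa_threshold, "dynamic",
                ifelse(params$orientation_sign * ga_x >= params$so_threshold,
                       "standing", "sedentary"))
  factor(lab, levels = activity_levels())
}

# BA/GA branches of the pipeline; computed once per recording so
# parameter sweeps do not refilter
filter_branches <- function(recording, constants = filter_constants()) {
  smoothed <- moving_average_filter(recording, constants$ma_window)
  list(
    ba = extract_body_acceleration(smoothed, constants)$samples,
    ga = extract_gravitational_acceleration(smoothed, constants)$samples,
    sampling_rate = recording$sampling_rate,
    n = nrow(recording$samples),
    subject_id = recording$subject_id
  )
}

# windowed features + labels from precomputed branches
classify_filtered <- function(branches, params) {
  rate <- branches$sampling_rate
  win <- segment_windows(branches$n, rate, params$window_size)
  k <- nrow(win)
  n_win_samples <- round(params$window_size * rate)
  # realized window duration; equals window_size whenever WS * rate is an
  # integer, and keeps time conservation exact otherwise
  win_dur <- n_win_samples / rate
  if (k > 0L) {
    used <- seq_len(k * n_win_samples)
    idx <- rep(seq_len(k), each = n_win_samples)
    sma <- rowsum(rowSums(abs(branches$ba[used, , drop = FALSE])), idx)[, 1L] /
      win_dur * params$count_scale
    ga_means <- rowsum(branches$ga[used, , drop = FALSE], idx) / n_win_samples
  } else {
    sma <- numeric(0)
    ga_means <- matrix(numeric(0), ncol = 3L)
  }
  labels <- classify_window(sma, ga_means[, 1L], params)
  features <- data.frame(
    window_index = seq_len(k) - 1L,
    start_s = (win[, "start"] - 1L) / rate,
    end_s = win[, "end"] / rate,
    sma_cps = as.numeric(sma),
    ga_x = as.numeric(ga_means[, 1L]),
    ga_y = as.numeric(ga_means[, 2L]),
    ga_z = as.numeric(ga_means[, 3L]),
    label = labels,
    row.names = NULL
  )
  structure(
    list(features = features, window_size = params$window_size,
         window_duration_s = win_dur,
         sampling_rate = rate,
         dropped_tail_s = attr(win, "dropped_samples") / rate,
         subject_id = branches$subject_id),
    class = "classified_series"
  )
}

#' Classify a full recording
#'
#' Runs the whole pipeline: moving-average noise removal, high-pass
#' (body acceleration) and low-pass (gravity) branches, segmentation of
#' both branches on the same window grid, per-window SMA and mean
#' gravity, and the decision tree.
#'
#' @param recording an [acc_recording()].
#' @param params an [algorithm_parameters()] object.
#' @return object of class `classified_series` with a `features` data
#'   frame (`window_index, start_s, end_s, sma_cps, ga_x, ga_y, ga_z,
#'   label`), the window size, and the dropped tail in seconds.
#' @export
classify_recording <- function(recording, params = algorithm_parameters()) {
  stopifnot(inherits(recording, "acc_recording"),
            inherits(params, "algorithm_parameters"))
  classify_filtered(filter_branches(recording, params$filter_constants),
                    params)
}

#' @export
print.classified_series <- function(x, ...) {
  cat(sprintf("<classified_series> subject %s: %d windows of %g s (tail %g s dropped)\n",
              x$subject_id, nrow(x$features), x$window_size, x$dropped_tail_s))
  print(class_totals(x))
  invisible(x)
}

#' Classified seconds per activity class
#'
#' @param series a `classified_series` from [classify_recording()].
#' @return named numeric vector of seconds per class (window count times
#'   the realized window duration); entries sum to the covered duration.
#' @export
class_totals <- function(series) {
  stopifnot(inherits(series, "classified_series"))
  tab <- table(series$features$label)
  stats::setNames(as.numeric(tab) * series$window_duration_s, names(tab))
}

#' Write per-window classification results to CSV
#'
#' @param series a `classified_series`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_window_csv <- function(series, path) {
  stopifnot(inherits(series, "classified_series"))
  utils::write.csv(series$features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
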