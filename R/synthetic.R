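#' Specification of one synthetic activity segment
#'
#' Describes a homogeneous stretch of thigh-worn accelerometer signal:
#' a constant gravity orientation given by the thigh angle from vertical
#' (longitudinal projection `g_x = cos(angle)`, the remainder on Z), an
#' optional gait-band body-acceleration component whose intensity is
#' expressed directly in the classifier's cps units, and white sensor
#' noise.
#'
#' @param label activity class of every second of the segment.
#' @param duration segment duration in whole seconds (> 0).
#' @param thigh_angle angle between gravity vector and thigh axis, in
#'   degrees from vertical (0 = upright), in `[0, 180]`.
#' @param ba_intensity target SMA of the generated body acceleration in
#'   cps (0 = no movement). Amplitudes are calibrated through the
#'   pipeline's own filters, so the expected measured SMA matches this
#'   value.
#' @param gait_frequency fundamental movement frequency in Hz (gait band
#'   is roughly 1-2 Hz); a first harmonic at twice this frequency is
#'   also generated.
#' @param noise_sd white Gaussian sensor-noise standard deviation in g.
#' @return object of class `activity_segment`.
#' @export
activity_segment <- function(label, duration, thigh_angle,
                             ba_intensity = 0, gait_frequency = 1.5,
                             noise_sd = 0.01) {
  label <- as.character(as_activity_label(label))
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (thigh_angle < 0 || thigh_angle > 180) {
    stop("thigh_angle must be in [0, 180] degrees", call. = FALSE)
  }
  if (ba_intensity < 0) stop("ba_intensity must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(label = label, duration = as.integer(round(duration)),
                 thigh_angle = thigh_angle, ba_intensity = ba_intensity,
                 gait_frequency = gait_frequency, noise_sd = noise_sd),
            class = "activity_segment")
}

# fixed multi-axis gait waveform (unit amplitude): fundamental on X and
# Y, first harmonic on Z; relative weights loosely mimic thigh
# accelerometry where the longitudinal axis dominates
.ba_wave <- function(tt, f) {
  cbind(sin(2 * pi * f * tt),
        0.6 * sin(2 * pi * f * tt + 1.3),
        0.4 * sin(2 * pi * 2 * f * tt + 0.7))
}

.calib_env <- new.env(parent = emptyenv())

# measured cps of the unit-amplitude waveform after the pipeline's own
# moving-average + high-pass filters; cached per (f, rate, constants)
.unit_cps <- function(gait_frequency, sampling_rate,
                      constants = filter_constants()) {
  key <- paste(gait_frequency, sampling_rate, constants$ma_window,
               constants$hp_cutoff, constants$butterworth_order, sep = "|")
  hit <- .calib_env[[key]]
  if (!is.null(hit)) return(hit)
  dur <- 24
  tt <- seq(0, dur - 1 / sampling_rate, by = 1 / sampling_rate)
  probe <- acc_recording(.ba_wave(tt, gait_frequency),
                         sampling_rate = sampling_rate)
  ba <- extract_body_acceleration(
    moving_average_filter(probe, constants$ma_window), constants)
  core <- which(tt >= 2 & tt < dur - 2)
  cps <- sum(abs(ba$samples[core, ])) / ((dur - 4))
  .calib_env[[key]] <- cps
  cps
}

#' Generate the raw samples of one activity segment
#'
#' Gravity contributes a constant `(cos theta, 0, sin theta)` g vector;
#' movement (if `ba_intensity > 0`) adds the gait waveform scaled so
#' that the SMA measured through the package's own moving-average and
#' high-pass filters equals `ba_intensity`; white Gaussian noise of sd
#' `noise_sd` is added to every axis. Uses the current RNG state; wrap
#' in a seed for reproducibility (the protocol generators do).
#'
#' @param spec an [activity_segment()].
#' @param sampling_rate Hz.
#' @param constants [filter_constants()] used for intensity calibration.
#' @return list with `samples` (n x 3 matrix in g) and `labels`
#'   (character, one per second).
#' @export
generate_segment <- function(spec, sampling_rate = 25,
                             constants = filter_constants()) {
  stopifnot(inherits(spec, "activity_segment"))
  if (2 * spec$gait_frequency >= sampling_rate / 2) {
    stop("gait_frequency (and its first harmonic) must be below Nyquist",
         call. = FALSE)
  }
  n <- spec$duration * sampling_rate
  theta <- spec$thigh_angle * pi / 180
  g <- matrix(rep(c(cos(theta), 0, sin(theta)), each = n), ncol = 3L)
  if (spec$ba_intensity > 0) {
    amp <- spec$ba_intensity /
      .unit_cps(spec$gait_frequency, sampling_rate, constants)
    tt <- seq(0, spec$duration - 1 / sampling_rate, by = 1 / sampling_rate)
    g <- g + amp * .ba_wave(tt, spec$gait_frequency)
  }
  if (spec$noise_sd > 0) {
    g <- g + matrix(stats::rnorm(3L * n, sd = spec$noise_sd), ncol = 3L)
  }
  list(samples = g, labels = rep(spec$label, spec$duration))
}

# assemble a list of activity_segment specs into recording + annotation
.assemble_protocol <- function(specs, sampling_rate, subject_id,
                               constants = filter_constants()) {
  parts <- lapply(specs, generate_segment, sampling_rate = sampling_rate,
                  constants = constants)
  samples <- do.call(rbind, lapply(parts, `[[`, "samples"))
  labels <- unlist(lapply(parts, `[[`, "labels"))
  list(
    recording = acc_recording(samples, sampling_rate = sampling_rate,
                              subject_id = subject_id),
    annotation = activity_annotation(labels),
    segments = specs
  )
}

#' Generate a fixed-activity-protocol (FAP) recording
#'
#' Emulates a prescribed sequence of activities with fixed order and
#' duration: standing, slow treadmill walking, sitting, faster treadmill
#' walking, lying, overground walking and biking. Default durations
#' yield exactly 480 s dynamic, 120 s standing and 300 s sedentary time.
#' Deterministic given the seed.
#'
#' @param seed integer RNG seed.
#' @param sampling_rate Hz (default 25).
#' @param noise_sd sensor noise sd in g (default 0.01).
#' @param subject_id subject identifier.
#' @return list with `recording`, `annotation` and the segment `segments`.
#' @export
generate_fap <- function(seed, sampling_rate = 25, noise_sd = 0.01,
                         subject_id = sprintf("fap_seed%d", seed)) {
  specs <- list(
    activity_segment("standing", 120, thigh_angle = 5, noise_sd = noise_sd),
    activity_segment("dynamic", 120, thigh_angle = 10, ba_intensity = 8,
                     gait_frequency = 1.2, noise_sd = noise_sd),   # walk 2 km/h
    activity_segment("sedentary", 180, thigh_angle = 85, noise_sd = noise_sd),  # sitting
    activity_segment("dynamic", 120, thigh_angle = 10, ba_intensity = 18,
                     gait_frequency = 1.9, noise_sd = noise_sd),   # walk 4 km/h
    activity_segment("sedentary", 120, thigh_angle = 90, noise_sd = noise_sd),  # lying
    activity_segment("dynamic", 120, thigh_angle = 10, ba_intensity = 15,
                     gait_frequency = 1.7, noise_sd = noise_sd),   # overground walk
    activity_segment("dynamic", 120, thigh_angle = 60, ba_intensity = 12,
                     gait_frequency = 1.0, noise_sd = noise_sd)    # biking
  )
  withr::with_seed(seed,
    .assemble_protocol(specs, sampling_rate, subject_id))
}

#' Generate a simulated-free-living-protocol (SFP) recording
#'
#' Emulates a participant freely choosing the order and duration of
#' activities of daily living: a shuffled, class-balanced sequence of
#' `n_adls` ADLs with durations drawn uniformly from 20-180 s, with
#' short (5-15 s) dynamic transfers inserted between consecutive
#' non-dynamic ADLs (walking between activity stations). Static ADLs
#' carry a small fidgeting intensity; standing uses thigh angles near
#' vertical and sedentary postures 70-100 degrees from vertical.
#'
#' With `mixed_adl = TRUE`, dynamic ADLs interleave 2-5 s standing
#' micro-pauses while keeping the whole ADL labeled dynamic; this
#' reproduces the rater convention of labeling a compound task (e.g.
#' setting a table) as one dynamic block even though it mixes standing
#' and movement, which inflates the apparent dynamic classification
#' error.
#'
#' @param seed integer RNG seed.
#' @param n_adls number of ADLs (>= 1).
#' @param sampling_rate Hz (default 25).
#' @param dynamic_cps range (min, max) of dynamic ADL intensities in cps.
#' @param static_cps range of fidgeting intensities for static ADLs in
#'   cps.
#' @param transfer_cps range of transfer intensities in cps.
#' @param noise_sd sensor noise sd in g.
#' @param mixed_adl interleave standing micro-pauses inside dynamic ADLs.
#' @param subject_id subject identifier.
#' @return list with `recording`, `annotation` and the segment `segments`.
#' @export
generate_sfp <- function(seed, n_adls = 12, sampling_rate = 25,
                         dynamic_cps = c(8, 18), static_cps = c(0.1, 1.5),
                         transfer_cps = c(8, 15), noise_sd = 0.01,
                         mixed_adl = FALSE,
                         subject_id = sprintf("sfp_seed%d", seed)) {
  if (n_adls < 1L) stop("n_adls must be >= 1", call. = FALSE)
  withr::with_seed(seed, {
    adl_labels <- sample(rep(activity_levels(), length.out = n_adls))
    specs <- list()
    prev <- NULL
    for (lab in adl_labels) {
      if (!is.null(prev) && prev != "dynamic" && lab != "dynamic") {
        specs <- c(specs, list(activity_segment(
          "dynamic", sample(5:15, 1L), thigh_angle = 15,
          ba_intensity = stats::runif(1, transfer_cps[1], transfer_cps[2]),
          gait_frequency = stats::runif(1, 1.2, 1.9), noise_sd = noise_sd)))
      }
      dur <- sample(20:180, 1L)
      if (lab == "dynamic") {
        specs <- c(specs, .sfp_dynamic_adl(dur, dynamic_cps, noise_sd,
                                           mixed_adl))
      } else if (lab == "standing") {
        specs <- c(specs, list(activity_segment(
          "standing", dur, thigh_angle = stats::runif(1, 0, 15),
          ba_intensity = stats::runif(1, static_cps[1], static_cps[2]),
          gait_frequency = stats::runif(1, 1.2, 2.2), noise_sd = noise_sd)))
      } else {
        specs <- c(specs, list(activity_segment(
          "sedentary", dur, thigh_angle = stats::runif(1, 70, 100),
          ba_intensity = stats::runif(1, static_cps[1], static_cps[2]),
          gait_frequency = stats::runif(1, 1.2, 2.2), noise_sd = noise_sd)))
      }
      prev <- lab
    }
    .assemble_protocol(specs, sampling_rate, subject_id)
  })
}

# one dynamic ADL: either a single movement block, or (mixed_adl)
# movement chunks interleaved with standing micro-pauses, all labeled
# dynamic
.sfp_dynamic_adl <- function(dur, dynamic_cps, noise_sd, mixed_adl) {
  cps <- stats::runif(1, dynamic_cps[1], dynamic_cps[2])
  f <- stats::runif(1, 1.0, 2.0)
  angle <- stats::runif(1, 5, 25)
  if (!mixed_adl) {
    return(list(activity_segment("dynamic", dur, thigh_angle = angle,
                                 ba_intensity = cps, gait_frequency = f,
                                 noise_sd = noise_sd)))
  }
  specs <- list()
  left <- dur
  moving <- TRUE
  while (left > 0L) {
    chunk <- if (moving) sample(5:12, 1L) else sample(2:5, 1L)
    chunk <- min(chunk, left)
    specs <- c(specs, list(activity_segment(
      "dynamic", chunk, thigh_angle = if (moving) angle else 5,
      ba_intensity = if (moving) cps else 0, gait_frequency = f,
      noise_sd = noise_sd)))
    left <- left - chunk
    moving <- !moving
  }
  specs
}

#' Generate a cohort of synthetic participants
#'
#' Draws one independent per-subject seed per participant from the
#' cohort seed, then generates each participant with [generate_fap()] or
#' [generate_sfp()].
#'
#' @param n_subjects cohort size.
#' @param protocol `"fap"` or `"sfp"`.
#' @param seed cohort-level RNG seed.
#' @param ... passed to the protocol generator.
#' @return list of participants, each a list with `recording`,
#'   `annotation`, `segments`; suitable for [compute_agreement()] and
#'   the optimizers.
#' @export
generate_cohort <- function(n_subjects, protocol = c("fap", "sfp"), seed = 1,
                            ...) {
  protocol <- match.arg(protocol)
  subject_seeds <- withr::with_seed(seed,
                                    sample.int(.Machine$integer.max - 1L,
                                               n_subjects))
  gen <- switch(protocol, fap = generate_fap, sfp = generate_sfp)
  lapply(seq_len(n_subjects), function(i) {
    gen(subject_seeds[i],
        subject_id = sprintf("%s_%02d", protocol, i), ...)
  })
}
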