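#' Fixed filter constants
#'
#' Constants of the three-stage preprocessing chain: a short moving
#' average removes sensor noise (NA); a 4th-order Butterworth high-pass
#' at 1 Hz extracts body acceleration (BA); a 4th-order Butterworth
#' low-pass at 1.25 Hz extracts gravitational acceleration (GA). These
#' are device/sampling-rate specific and, unlike the three classifier
#' parameters, are not subject to optimization.
#'
#' @param ma_window moving-average window in seconds (default 0.12 s).
#' @param hp_cutoff high-pass cutoff in Hz (default 1 Hz).
#' @param lp_cutoff low-pass cutoff in Hz (default 1.25 Hz).
#' @param butterworth_order per-pass Butterworth design order (default 4).
#' @return object of class `filter_constants`.
#' @export
filter_constants <- function(ma_window = 0.12, hp_cutoff = 1.0,
                             lp_cutoff = 1.25, butterworth_order = 4L) {
  if (ma_window <= 0) stop("ma_window must be positive", call. = FALSE)
  if (hp_cutoff <= 0 || lp_cutoff <= 0) {
    stop("filter cutoffs must be positive", call. = FALSE)
  }
  if (butterworth_order < 1) stop("butterworth_order must be >= 1",
                                  call. = FALSE)
  structure(list(ma_window = ma_window, hp_cutoff = hp_cutoff,
                 lp_cutoff = lp_cutoff,
                 butterworth_order = as.integer(butterworth_order)),
            class = "filter_constants")
}

# centered moving average of one axis; k odd; shrinking window at edges
.moving_average_1d <- function(x, k) {
  n <- length(x)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Moving-average noise filter
#'
#' Centered per-axis moving average over `round(ma_window * rate)`
#' samples (forced odd so the filter is symmetric). Edges use the
#' shrunken window, i.e. the mean of the available samples; output
#' length equals input length.
#'
#' @param recording an [acc_recording()].
#' @param ma_window window length in seconds (default 0.12 s, which is 3
#'   samples at 25 Hz).
#' @return filtered [acc_recording()].
#' @export
moving_average_filter <- function(recording, ma_window = 0.12) {
  stopifnot(inherits(recording, "acc_recording"))
  if (!is.numeric(ma_window) || ma_window <= 0) {
    stop("ma_window must be positive", call. = FALSE)
  }
  k <- round(ma_window * recording$sampling_rate)
  if (k < 1) stop("ma_window shorter than one sample period", call. = FALSE)
  if (k %% 2L == 0L) k <- k + 1L
  out <- recording
  out$samples <- apply(recording$samples, 2L, .moving_average_1d, k = k)
  colnames(out$samples) <- c("ax", "ay", "az")
  out
}

# evaluate polynomial sum(p[i] * u^(i-1)) at complex points u (ascending
# powers, i.e. p are coefficients of z^0, z^-1, ... with u = exp(-i w))
.polyval_asc <- function(p, u) {
  r <- rep(0 + 0i, length(u))
  for (c in rev(p)) r <- r * u + c
  r
}

# Zero-phase Butterworth filtering of one axis. The squared magnitude
# response of the designed filter (the exact steady-state response of a
# forward-backward pass) is applied in the frequency domain to the
# mirror-extended signal. Mirror extension makes the circular signal
# continuous at the seam and keeps the operation exactly linear,
# exactly zero-phase, and symmetry-preserving.
.butter_zero_phase_1d <- function(x, sampling_rate, cutoff, order, type) {
  ba <- signal::butter(order, W = cutoff / (sampling_rate / 2), type = type)
  n <- length(x)
  ext <- c(x, rev(x))
  m <- 2L * n
  u <- exp(-2i * pi * (seq_len(m) - 1L) / m)
  H <- .polyval_asc(ba$b, u) / .polyval_asc(ba$a, u)
  g <- Re(H * Conj(H))
  Re(stats::fft(stats::fft(ext) * g, inverse = TRUE))[seq_len(n)] / m
}

# causal single-pass alternative (phase-shifting); offline analysis uses
# the zero-phase default
.butter_causal_1d <- function(x, sampling_rate, cutoff, order, type) {
  ba <- signal::butter(order, W = cutoff / (sampling_rate / 2), type = type)
  as.numeric(signal::filter(ba, x))
}

.apply_butter <- function(recording, cutoff, order, type, zero_phase) {
  stopifnot(inherits(recording, "acc_recording"))
  if (cutoff >= recording$sampling_rate / 2) {
    stop(sprintf("cutoff %g Hz must be below the Nyquist frequency %g Hz",
                 cutoff, recording$sampling_rate / 2), call. = FALSE)
  }
  fn <- if (zero_phase) .butter_zero_phase_1d else .butter_causal_1d
  out <- recording
  out$samples <- apply(recording$samples, 2L, fn,
                       sampling_rate = recording$sampling_rate,
                       cutoff = cutoff, order = order, type = type)
  colnames(out$samples) <- c("ax", "ay", "az")
  out
}

#' Extract body acceleration (BA)
#'
#' Removes the gravitational component with a per-axis zero-phase
#' Butterworth high-pass of the design order and cutoff in `constants`.
#' The zero-phase (forward-backward) formulation keeps BA and GA
#' time-aligned for windowing; its effective amplitude response is the
#' squared single-pass response.
#'
#' @param recording an [acc_recording()], normally already
#'   noise-filtered with [moving_average_filter()].
#' @param constants a [filter_constants()] object.
#' @param zero_phase apply forward-backward (default) or causal
#'   single-pass filtering.
#' @return [acc_recording()] holding the body-acceleration component.
#' @export
extract_body_acceleration <- function(recording,
                                      constants = filter_constants(),
                                      zero_phase = TRUE) {
  .apply_butter(recording, constants$hp_cutoff, constants$butterworth_order,
                "high", zero_phase)
}

#' Extract gravitational acceleration (GA)
#'
#' Removes the body-movement component with a per-axis zero-phase
#' Butterworth low-pass of the design order and cutoff in `constants`,
#' leaving the slowly varying gravity projection that encodes sensor
#' (and hence thigh) orientation.
#'
#' @inheritParams extract_body_acceleration
#' @return [acc_recording()] holding the gravitational component.
#' @export
extract_gravitational_acceleration <- function(recording,
                                               constants = filter_constants(),
                                               zero_phase = TRUE) {
  .apply_butter(recording, constants$lp_cutoff, constants$butterworth_order,
                "low", zero_phase)
}
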