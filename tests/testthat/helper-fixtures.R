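# shared fixtures: small recordings built in code

make_recording <- function(mat, rate = 25, subject_id = "s1") {
  acc_recording(mat, sampling_rate = rate, subject_id = subject_id)
}

random_recording <- function(n, rate = 25, sd = 0.5) {
  make_recording(matrix(rnorm(3L * n, sd = sd), ncol = 3L), rate = rate)
}

constant_recording <- function(g = c(1, 0, 0), seconds = 60, rate = 25) {
  n <- seconds * rate
  make_recording(matrix(rep(g, each = n), ncol = 3L), rate = rate)
}

# literal, loop-based reference classifier: same filter stages, but
# per-sample moving average and per-window sums written as explicit
# loops over axes and samples
reference_classify <- function(recording, params) {
  rate <- recording$sampling_rate
  x <- recording$samples
  n <- nrow(x)
  k <- round(params$filter_constants$ma_window * rate)
  if (k %% 2 == 0) k <- k + 1
  h <- (k - 1) / 2
  sm <- x
  for (ax in 1:3) {
    for (i in 1:n) {
      lo <- max(1, i - h); hi <- min(n, i + h)
      sm[i, ax] <- mean(x[lo:hi, ax])
    }
  }
  smr <- recording; smr$samples <- sm
  ba <- extract_body_acceleration(smr, params$filter_constants)$samples
  ga <- extract_gravitational_acceleration(smr, params$filter_constants)$samples
  N <- round(params$window_size * rate)
  n_win <- floor(n / N)
  labels <- character(n_win)
  for (j in seq_len(n_win)) {
    idx <- ((j - 1) * N + 1):(j * N)
    sma <- 0
    for (ax in 1:3) for (i in idx) sma <- sma + abs(ba[i, ax])
    sma <- sma / params$window_size * params$count_scale
    gx <- 0
    for (i in idx) gx <- gx + ga[i, 1]
    gx <- gx / N
    labels[j] <- if (sma >= params$pa_threshold) "dynamic"
      else if (params$orientation_sign * gx >= params$so_threshold) "standing"
      else "sedentary"
  }
  labels
}
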