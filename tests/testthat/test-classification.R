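test_that("segmentation yields floor(n/N) complete windows, tail dropped", {
  win <- segment_windows(7500, 25, 2)
  expect_equal(nrow(win), 150L)
  expect_equal(unname(win[1, ]), c(1L, 50L))
  expect_equal(unname(win[150, ]), c(7451L, 7500L))
  expect_equal(attr(win, "dropped_samples"), 0L)

  win2 <- segment_windows(7525, 25, 2)
  expect_equal(nrow(win2), 150L)
  expect_equal(attr(win2, "dropped_samples"), 25L)

  win3 <- segment_windows(10, 25, 2)  # N = 50 > n: valid empty segmentation
  expect_equal(nrow(win3), 0L)
  expect_error(segment_windows(100, 25, 0.001), "at least one sample")
})

test_that("SMA matches hand sums and the literal double-loop formula", {
  expect_equal(compute_sma_cps(matrix(0, 50, 3), 2), 0)
  w <- cbind(rep(0.1, 50), 0, 0)
  expect_equal(compute_sma_cps(w, 2), 2.5)

  set.seed(31)
  for (rep_i in 1:5) {
    w <- matrix(rnorm(50 * 3), 50, 3)
    brute <- 0
    for (ax in 1:3) for (i in 1:50) brute <- brute + abs(w[i, ax])
    expect_lt(abs(compute_sma_cps(w, 2) - brute / 2), 1e-12)
  }
  expect_error(compute_sma_cps(matrix(numeric(0), 0, 3), 2), "empty")
})

test_that("mean gravity is the per-axis loop mean", {
  w <- matrix(rep(c(0.8, 0, 0.6), each = 10), 10, 3)
  expect_equal(unname(compute_mean_gravity(w)), c(0.8, 0, 0.6))
  w2 <- cbind(rep(c(1, -1), 10), 0, 0)
  expect_equal(unname(compute_mean_gravity(w2))[1], 0)

  set.seed(32)
  w3 <- matrix(rnorm(60), 20, 3)
  brute <- c(0, 0, 0)
  for (ax in 1:3) for (i in 1:20) brute[ax] <- brute[ax] + w3[i, ax]
  expect_lt(max(abs(compute_mean_gravity(w3) - brute / 20)), 1e-12)
  expect_error(compute_mean_gravity(matrix(numeric(0), 0, 3)), "empty")
})

test_that("decision tree applies PA and orientation thresholds inclusively", {
  p <- algorithm_parameters(window_size = 2, pa_threshold = 7,
                            so_threshold = 0.8)
  expect_equal(as.character(classify_window(10, 0.5, p)), "dynamic")
  expect_equal(as.character(classify_window(3, 0.95, p)), "standing")
  expect_equal(as.character(classify_window(3, 0.17, p)), "sedentary")
  # boundaries are inclusive: sma == PA Th is dynamic, g_x == SO Th standing
  expect_equal(as.character(classify_window(7, 0.95, p)), "dynamic")
  expect_equal(as.character(classify_window(6.999, 0.8, p)), "standing")
  # orientation_sign flips the axis for an inverted sensor
  pinv <- algorithm_parameters(orientation_sign = -1)
  expect_equal(as.character(classify_window(3, -0.95, pinv)), "standing")
})

test_that("static recordings classify by posture; calibrated walking is dynamic", {
  p <- algorithm_parameters()
  upright <- classify_recording(constant_recording(c(1, 0, 0), 60), p)
  expect_true(all(upright$features$label == "standing"))
  reclined <- classify_recording(constant_recording(c(0.17, 0, 0.98), 60), p)
  expect_true(all(reclined$features$label == "sedentary"))

  walk <- withr::with_seed(77, generate_segment(
    activity_segment("dynamic", 60, thigh_angle = 10, ba_intensity = 15,
                     gait_frequency = 1.6), 25))
  series <- classify_recording(make_recording(walk$samples), p)
  expect_gte(mean(series$features$label == "dynamic"), 0.95)
})

test_that("class totals count windows times window size", {
  fap <- generate_fap(2)
  series <- classify_recording(fap$recording)
  tot <- class_totals(series)
  tab <- table(series$features$label)
  expect_equal(unname(tot), as.numeric(tab) * 2)
  expect_equal(sum(tot) + series$dropped_tail_s,
               recording_duration(fap$recording))
})

test_that("time is conserved for random duration/window combinations", {
  set.seed(41)
  for (rep_i in 1:25) {
    n <- sample(30:400, 1)
    ws <- sample(c(0.5, 1, 2, 3, 5), 1)
    rec <- random_recording(n)
    series <- classify_recording(rec, algorithm_parameters(window_size = ws))
    expect_lt(abs(sum(class_totals(series)) + series$dropped_tail_s -
                    recording_duration(rec)), 1 / 25 + 1e-12)
  }
})

test_that("adding a constant offset leaves SMA and the dynamic split unchanged", {
  set.seed(42)
  rec <- random_recording(500, sd = 0.2)
  shifted <- rec
  shifted$samples <- sweep(rec$samples, 2, c(0.9, -0.4, 0.3), "+")
  p <- algorithm_parameters()
  a <- classify_recording(rec, p)
  b <- classify_recording(shifted, p)
  expect_lt(max(abs(a$features$sma_cps - b$features$sma_cps)), 1e-6)
  expect_equal(a$features$sma_cps >= p$pa_threshold,
               b$features$sma_cps >= p$pa_threshold)
})

test_that("raising thresholds never increases the affected class time", {
  fap <- generate_fap(3)
  pa_grid <- c(3, 5, 7, 9, 12)
  dyn <- vapply(pa_grid, function(pa) {
    class_totals(classify_recording(
      fap$recording, algorithm_parameters(pa_threshold = pa)))["dynamic"]
  }, numeric(1))
  expect_true(all(diff(dyn) <= 0))

  so_grid <- c(0.5, 0.7, 0.8, 0.9, 0.99)
  stand <- vapply(so_grid, function(so) {
    class_totals(classify_recording(
      fap$recording, algorithm_parameters(so_threshold = so)))["standing"]
  }, numeric(1))
  expect_true(all(diff(stand) <= 0))
})

test_that("pipeline labels match the literal loop-based reference", {
  set.seed(43)
  for (rep_i in 1:3) {
    rec <- random_recording(250, sd = 0.3)  # 10 s at 25 Hz
    p <- algorithm_parameters(window_size = 1, pa_threshold = 5)
    series <- classify_recording(rec, p)
    expect_equal(as.character(series$features$label),
                 reference_classify(rec, p))
  }
})

test_that("parameter invariants are enforced", {
  expect_error(algorithm_parameters(window_size = 0), "positive")
  expect_error(algorithm_parameters(pa_threshold = -1), "positive")
  expect_error(algorithm_parameters(so_threshold = 1.5), "\\(0, 1\\]")
  expect_error(algorithm_parameters(orientation_sign = 2), "\\+1 or -1")
  expect_equal(floor(orientation_angle(0.8)), 36)
})
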