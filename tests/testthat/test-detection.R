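test_that("noise-free detection is exact for all disciplines", {
  # swim, 30 cycles/min over 60 s -> 60 strokes
  g <- clean_recording("swim", 60, cadence = 60)
  expect_equal(detect_swim_strokes(g$recording)$count, 60)
  # cycle, 90 rev/min = 180 pedal strokes/min
  g <- clean_recording("cycle", 60, cadence = 180)
  expect_equal(detect_cycle_pedal_strokes(g$recording)$count, 180)
  # run, 80 strides/min
  g <- clean_recording("run", 60, cadence = 80)
  expect_equal(detect_run_strides(g$recording)$count, 80)
})

test_that("noisy detection stays within a few percent of ground truth", {
  g <- noisy_recording("swim", 120, seed = 7, noise_snr_db = 10,
                       jitter_cv = 0, spike_rate_per_min = 0)
  ev <- detect_swim_strokes(g$recording)
  expect_lte(abs(ev$count - g$truth$count) / g$truth$count, 0.02)

  g <- noisy_recording("cycle", 120, seed = 3, noise_snr_db = 10,
                       jitter_cv = 0.05, spike_rate_per_min = 2)
  ev <- detect_cycle_pedal_strokes(g$recording)
  expect_lte(abs(ev$count - g$truth$count) / g$truth$count, 0.03)
})

test_that("cycling candidates require antero-posterior confirmation", {
  g <- clean_recording("cycle", 60, cadence = 180)
  rec <- g$recording
  rec$acc_ap <- rep(0, nrow(rec))
  expect_equal(detect_cycle_pedal_strokes(rec)$count, 0)
})

test_that("a pure-noise channel below the floor yields zero events", {
  g <- clean_recording("swim", 60, cadence = 60)
  rec <- g$recording
  set.seed(2)
  rec$acc_ml <- rnorm(nrow(rec), 0, 0.05)
  expect_equal(detect_swim_strokes(rec)$count, 0)
})

test_that("missing channels and degenerate recordings raise classed errors", {
  g <- clean_recording("run", 30)
  rec <- g$recording
  rec$acc_v <- NULL
  expect_error(detect_run_strides(rec), class = "missing_channel")
  rec2 <- g$recording
  rec2$acc_ml <- NA_real_
  expect_error(detect_swim_strokes(rec2), class = "missing_channel")
  tiny <- imu_recording(0.01 * (0:5), rnorm(6), rnorm(6), rnorm(6),
                        rnorm(6), rnorm(6), rnorm(6), sample_rate_hz = 100)
  expect_error(detect_run_strides(tiny), class = "degenerate_input")
})

test_that("a one-sample artifact spike between impacts does not change the stride count", {
  g <- clean_recording("run", 60, cadence = 80, seed = 5)
  base <- detect_run_strides(g$recording)
  rec <- g$recording
  ev <- g$truth$event_times_s
  mid <- (ev[[10]] + ev[[11]]) / 2  # between two impacts
  k <- round(mid * 100) + 1
  rec$acc_v[[k]] <- rec$acc_v[[k]] + 5 * 8
  withspike <- detect_run_strides(rec)
  expect_equal(withspike$count, base$count)
})

test_that("detected counts equal ground truth across a cadence sweep (noise-free oracle)", {
  sweeps <- list(swim = seq(50, 80, length.out = 5),
                 cycle = seq(150, 200, length.out = 5),
                 run = seq(75, 95, length.out = 5))
  for (disc in names(sweeps)) {
    for (rate in sweeps[[disc]]) {
      g <- clean_recording(disc, 60, cadence = rate, seed = 1)
      ev <- detect_events(g$recording, disc)
      expect_equal(ev$count, g$truth$count,
                   info = sprintf("%s at %.1f events/min", disc, rate))
    }
  }
})

test_that("detection accuracy does not improve as noise increases", {
  snrs <- c(30, 20, 10, 5)
  mean_acc <- sapply(snrs, function(snr) {
    accs <- sapply(1:20, function(seed) {
      g <- noisy_recording("swim", 60, seed = 300 + seed,
                           noise_snr_db = snr, jitter_cv = 0.05,
                           spike_rate_per_min = 2)
      count_accuracy(detect_swim_strokes(g$recording), g$truth)
    })
    mean(accs)
  })
  expect_true(all(diff(mean_acc) <= 1e-9))
})

test_that("shifting a recording shifts event times and preserves the count", {
  g <- clean_recording("swim", 60, cadence = 60, seed = 9)
  rec <- g$recording
  k <- 25  # 0.25 s
  n <- nrow(rec)
  shift <- function(x) x[(k + 1):n]
  rec2 <- imu_recording((0:(n - k - 1)) / 100, shift(rec$acc_ml),
                        shift(rec$acc_ap), shift(rec$acc_v),
                        shift(rec$gyr_yaw), shift(rec$gyr_roll),
                        shift(rec$gyr_pitch), 100, "swim")
  e1 <- detect_swim_strokes(rec)
  e2 <- detect_swim_strokes(rec2)
  expect_equal(e2$count, e1$count)
  expect_equal(e2$event_times_s, e1$event_times_s - k / 100,
               tolerance = 0.02)
})

test_that("average cadence arithmetic and validation", {
  ev <- event_series(seq(0.5, 59.5, 1), "swim")
  expect_equal(average_cadence(ev, 60), 60)
  expect_equal(average_cadence(event_series(numeric(0)), 60), 0)
  ev45 <- event_series(seq(0.1, 29.9, length.out = 45), "run")
  expect_equal(average_cadence(ev45, 30), 90)
  expect_error(average_cadence(ev, 0), class = "invalid_parameter")
})

test_that("detection parameter validation enforces the refractory range", {
  expect_error(detection_params(3, min_interval_s = 0.2),
               class = "invalid_parameter")
  expect_error(detection_params(3, min_interval_s = 0.6),
               class = "invalid_parameter")
  expect_error(detection_params(-1, 0.3), class = "invalid_parameter")
  p <- detection_params(3, 0.5)
  expect_s3_class(p, "detection_params")
})

test_that("per-discipline detection config round-trips through YAML", {
  params <- list(swim = detection_params(2.5, 0.45),
                 run = default_detection_params("run"))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_detection_config(params, path)
  back <- read_detection_config(path)
  expect_equal(back$swim$cutoff_hz, 2.5)
  expect_equal(back$swim$min_interval_s, 0.45)
  expect_equal(back$run$cutoff_hz, 8)
})
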