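test_that("profile consistency check accepts matched speed/step/cadence and rejects mismatch", {
  # 0.50 m x 120 steps/min / 60 = 1.0 m/s
  expect_s3_class(gait_profile(walking_speed = 1.0, step_length_mean = 50,
                               cadence = 120), "gait_profile")
  expect_error(gait_profile(walking_speed = 1.0, step_length_mean = 40,
                            cadence = 120), "inconsistent profile")
  expect_error(gait_profile(stance_fraction = 1.2), "stance_fraction")
})

test_that("generator rejects stance fractions implying flight", {
  p <- gait_profile(stance_fraction = 0.4)
  expect_error(generate_trajectories(p), "double support")
})

test_that("noiseless relative AP extrema coincide with ground-truth event times", {
  p <- gait_profile(noise_sd_trajectory = 0, seed = 11)
  g <- generate_trajectories(p)
  t <- g$trial$time_s
  stride <- 120 / p$cadence
  fs <- p$trajectory_rate
  for (side in c("left", "right")) {
    rel <- g$trial$rel_truth[[side]]
    for (tc in g$events[[side]]$contact) {
      win <- which(abs(t - tc) <= 0.3 * stride)
      if (length(win) < 3 || min(win) == 1 || max(win) == length(t)) next
      t_max <- t[win[which.max(rel[win])]]
      # construction places the maximum at the contact; on the sampled
      # grid the argmax is the nearest frame
      expect_lt(abs(t_max - tc), 0.5 / fs + 1e-9)
    }
    for (to in g$events[[side]]$off) {
      win <- which(abs(t - to) <= 0.3 * stride)
      if (length(win) < 3 || min(win) == 1 || max(win) == length(t)) next
      t_min <- t[win[which.min(rel[win])]]
      expect_lt(abs(t_min - to), 0.5 / fs + 1e-9)
    }
  }
})

test_that("ground-truth contact count matches the stride count of the construction", {
  p <- gait_profile(seed = 1)
  g <- generate_trajectories(p)
  duration <- (p$walkway_length + 1) / p$walking_speed
  expected <- floor(duration * p$cadence / 120)  # strides completed
  n_right <- length(g$events$right$contact)
  expect_lte(abs(n_right - expected), 1)
})

test_that("identical profile and seed give bit-identical trials", {
  a <- synthetic_trial(gait_profile(seed = 7))
  b <- synthetic_trial(gait_profile(seed = 7))
  expect_identical(a$trajectories$points, b$trajectories$points)
  expect_identical(a$emg$signals, b$emg$signals)
  expect_identical(a$events_truth, b$events_truth)
  expect_identical(a$stim_truth$intervals, b$stim_truth$intervals)
})

test_that("ground-truth footfall spacing reproduces the profile step lengths", {
  p <- gait_profile(step_length_asymmetry = 10, noise_sd_trajectory = 0, seed = 3)
  g <- generate_trajectories(p)
  ff <- g$trial$footfalls
  d <- diff(ff$ap_cm)
  stepped <- ff$side[-1]
  expect_equal(mean(d[stepped == "right"]), 55, tolerance = 0.02)
  expect_equal(mean(d[stepped == "left"]), 45, tolerance = 0.02)
})

test_that("clean single-burst EMG energy is confined to the burst window", {
  p <- gait_profile(noise_sd_emg = 0, powerline_amplitude = 0, seed = 5)
  g <- generate_trajectories(p)
  b <- list(muscle_burst("TA", "right", 0.30, 0.10))
  rec <- generate_emg(p, b, g$events)
  t <- (seq_len(nrow(rec$signals)) - 1) / rec$sampling_rate
  contacts <- g$events$right$contact
  stride <- stats::median(diff(contacts))
  inside <- rep(FALSE, length(t))
  for (c0 in contacts)
    inside <- inside | (t >= c0 + 0.30 * stride - 1e-9 &
                          t <= c0 + 0.40 * stride + 1e-9)
  x <- rec$signals[, "TA_R"]
  expect_gt(sum(x[inside]^2), 0)
  expect_equal(sum(x[!inside]^2), 0)
})

test_that("zero-amplitude bursts leave pure powerline interference", {
  p <- gait_profile(noise_sd_emg = 0, powerline_amplitude = 0.3, seed = 6)
  g <- generate_trajectories(p)
  rec <- generate_emg(p, list(muscle_burst("VL", "left", 0.1, 0.2, 0)), g$events)
  x <- rec$signals[, "VL_L"]
  t <- (seq_along(x) - 1) / rec$sampling_rate
  basis <- do.call(cbind, lapply(1:5, function(k)
    cbind(sin(2 * pi * 50 * k * t), cos(2 * pi * 50 * k * t))))
  res <- stats::lm.fit(basis, x)$residuals
  expect_lt(sum(res^2), 1e-12 * sum(x^2))
  expect_true(all(rec$truth_env[, "VL_L"] == 0))
})

test_that("unknown muscle labels are rejected", {
  expect_error(muscle_burst("BICEPS", "left", 0.1, 0.2), "unknown muscle")
})

test_that("fixtures round-trip losslessly through the readers", {
  p <- gait_profile(seed = 9, walkway_length = 0.7)
  trial <- synthetic_trial(p)
  dir <- withr::local_tempdir()
  paths <- write_fixture(trial, dir)

  tr2 <- read_trajectories(paths[["trajectories"]], walkway_length = 0.7)
  for (nm in names(trial$trajectories$points))
    expect_equal(tr2$points[[nm]], trial$trajectories$points[[nm]],
                 tolerance = 1e-9)
  expect_equal(tr2$time_s, trial$trajectories$time_s, tolerance = 1e-9)

  ev2 <- read_events(paths[["events"]])
  expect_equal(ev2$right$contact, trial$events_truth$right$contact,
               tolerance = 1e-9)
  expect_equal(ev2$left$off, trial$events_truth$left$off, tolerance = 1e-9)

  emg2 <- read_emg(paths[["emg"]])
  expect_equal(unname(emg2$signals), unname(trial$emg$signals),
               tolerance = 1e-9)

  p2 <- read_profile(paths[["profile"]])
  expect_equal(unclass(p2), unclass(p), tolerance = 1e-12)

  sch2 <- read_schedule(paths[["schedule"]])
  expect_equal(sch2$cycle_duration_ms, trial$schedule$cycle_duration_ms)
  expect_equal(lapply(sch2$channels, unclass),
               lapply(trial$schedule$channels, unclass))
})

test_that("a two-stride trial writes two contact rows per side", {
  # duration (0.7 + 1) / 0.8 = 2.125 s; stride 1.25 s -> contacts at
  # {0, 1.25} (right) and {0.625, 1.875} (left)
  p <- gait_profile(seed = 9, walkway_length = 0.7)
  trial <- synthetic_trial(p)
  dir <- withr::local_tempdir()
  paths <- write_fixture(trial, dir)
  ev <- utils::read.csv(paths[["events"]])
  counts <- table(ev$side[ev$event == "foot_contact"])
  expect_equal(unname(counts[["left"]]), 2)
  expect_equal(unname(counts[["right"]]), 2)
})

test_that("an empty trial is refused, not written as empty files", {
  p <- gait_profile(seed = 9)
  trial <- synthetic_trial(p)
  trial$trajectories <- NULL
  expect_error(write_fixture(trial, withr::local_tempdir()), "empty trial")
})
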