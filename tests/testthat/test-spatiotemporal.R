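test_that("step locations are medians of the ankle position over single support", {
  t <- seq(0, 3, by = 1 / 30)
  n <- length(t)
  ev <- one_interval_events()   # right single support over [1.0, 2.0] s
  mk <- function(right_x) trajectory_trial(
    time_s = t,
    points = list(ankle_L = data.frame(x = 0.8 * t, y = 0.06, z = 0.08),
                  ankle_R = data.frame(x = right_x, y = 0.05, z = 0.08),
                  spine_base = data.frame(x = 0.8 * t, y = 0, z = 0.95)),
    sampling_rate = 30)
  # stationary ankle at (3.00 m, 0.05 m)
  locs <- step_locations(mk(rep(3, n)), ev)
  expect_equal(locs$ap_cm, 300)
  expect_equal(locs$ml_cm, 5)
  # one outlier among {299, 300, 320} cm leaves the median at 300
  xr <- rep(3, n)
  inside <- which(t >= 1 & t <= 2)
  xr[inside] <- 3.00
  xr[inside[1]] <- 2.99
  xr[inside[2]] <- 3.20
  expect_equal(step_locations(mk(xr), ev)$ap_cm, 300)
})

test_that("zero-noise step locations match the constructed footfalls", {
  g <- generate_trajectories(gait_profile(noise_sd_trajectory = 0, seed = 13))
  locs <- step_locations(g$trial, g$events)
  ff <- g$trial$footfalls
  expect_equal(nrow(locs), nrow(ff))
  expect_lt(max(abs(locs$ap_cm - ff$ap_cm)), 0.5)
  expect_lt(max(abs(locs$ml_cm - ff$ml_cm)), 0.5)
})

test_that("step length is the signed AP difference and width the absolute ML difference", {
  locs <- data.frame(side = c("left", "right"), t_start = c(0, 1),
                     t_end = c(0.5, 1.5), t_mid = c(0.25, 1.25),
                     ap_cm = c(200, 250), ml_cm = c(10, -5))
  s <- step_length_width(locs)
  expect_equal(s$length_cm, 50)
  expect_equal(s$width_cm, 15)
  expect_false(s$backward)
  # identical consecutive locations
  locs2 <- locs
  locs2[2, c("ap_cm", "ml_cm")] <- locs[1, c("ap_cm", "ml_cm")]
  s2 <- step_length_width(locs2)
  expect_equal(s2$length_cm, 0)
  expect_equal(s2$width_cm, 0)
  # same-side pairs are skipped with a message
  locs3 <- rbind(locs, data.frame(side = "right", t_start = 2, t_end = 2.5,
                                  t_mid = 2.25, ap_cm = 300, ml_cm = 5))
  expect_message(s3 <- step_length_width(locs3), "skipped")
  expect_equal(nrow(s3), 1)
  # backward steps are flagged, not clamped
  locs4 <- locs
  locs4$ap_cm <- c(250, 200)
  expect_message(s4 <- step_length_width(locs4), "backward")
  expect_equal(s4$length_cm, -50)
  expect_true(s4$backward)
})

test_that("cadence follows (n - 1) / span * 60 over pooled contacts", {
  expect_equal(st_cadence(seq(0, 6, length.out = 11)), 100)
  expect_equal(st_cadence(c(0, 1)), 60)
  expect_error(st_cadence(3), ">= 2 foot contacts")
})

test_that("walking speed uses interpolated 2 m and 8 m crossings", {
  t <- seq(0, 25, by = 1 / 30)
  mk <- function(x) trajectory_trial(
    time_s = t,
    points = list(ankle_L = data.frame(x = x, y = 0.06, z = 0.08),
                  ankle_R = data.frame(x = x, y = -0.06, z = 0.08),
                  spine_base = data.frame(x = x, y = 0, z = 0.95)),
    sampling_rate = 30)
  expect_equal(walking_speed(mk(-0.5 + 1.0 * t)), 1.0, tolerance = 1e-9)
  # slow before the 2 m line, fast after: the window excludes the slow part
  x <- ifelse(t <= 5, 0.5 * t - 0.5, 2 + 1.0 * (t - 5))
  expect_equal(walking_speed(mk(x)), 1.0, tolerance = 1e-9)
  # not traversed
  expect_error(walking_speed(mk(0.2 * t - 0.5)), "not fully traversed")
})

test_that("synthetic walking speed is recovered despite within-stride modulation", {
  p <- gait_profile(walking_speed = 0.8, noise_sd_trajectory = 0, seed = 15)
  g <- generate_trajectories(p)
  expect_equal(walking_speed(g$trial), 0.8, tolerance = 0.025)
})

test_that("step-length asymmetry is recovered from the summary", {
  lens <- list(left = c(), right = c())
  for (seed in 101:110) {
    p <- gait_profile(step_length_asymmetry = 10, noise_sd_trajectory = 0.3,
                      seed = seed)
    g <- generate_trajectories(p)
    s <- spatiotemporal_summary(g$trial, g$events)
    for (side in c("left", "right"))
      lens[[side]] <- c(lens[[side]],
                        s$steps$length_cm[s$steps$side == side])
  }
  expect_equal(mean(lens$right), 55, tolerance = 0.04)
  expect_equal(mean(lens$left), 45, tolerance = 0.04)
})

test_that("summary differences are signed parameter changes", {
  g1 <- generate_trajectories(gait_profile(walking_speed = 0.5, cadence = 90,
                                           step_length_mean = 100 * 0.5 * 60 / 90,
                                           noise_sd_trajectory = 0, seed = 1))
  g2 <- generate_trajectories(gait_profile(walking_speed = 0.6, cadence = 90,
                                           step_length_mean = 100 * 0.6 * 60 / 90,
                                           noise_sd_trajectory = 0, seed = 2))
  s1 <- spatiotemporal_summary(g1$trial, g1$events)
  s2 <- spatiotemporal_summary(g2$trial, g2$events)
  d0 <- spatiotemporal_diff(s1, s1)
  expect_true(all(unlist(d0) == 0))
  expect_equal(spatiotemporal_diff(s1, s2)$walking_speed_ms, 0.1,
               tolerance = 0.05)
})

test_that("samples outside the 2-8 m window do not change the summary", {
  p <- gait_profile(noise_sd_trajectory = 0, seed = 17)
  g <- generate_trajectories(p)
  full <- spatiotemporal_summary(g$trial, g$events)
  keep <- g$trial$points$spine_base$x >= 0.5 & g$trial$points$spine_base$x <= 9.5
  cut <- g$trial
  cut$time_s <- cut$time_s[keep]
  for (nm in names(cut$points)) cut$points[[nm]] <- cut$points[[nm]][keep, ]
  ev_cut <- gait_events(
    left = lapply(g$events$left, function(v)
      v[v >= min(cut$time_s) & v <= max(cut$time_s)]),
    right = lapply(g$events$right, function(v)
      v[v >= min(cut$time_s) & v <= max(cut$time_s)]),
    source = "truth")
  trimmed <- spatiotemporal_summary(cut, ev_cut)
  expect_equal(trimmed$walking_speed_ms, full$walking_speed_ms)
  expect_equal(trimmed$step_length_cm$mean, full$step_length_cm$mean)
  expect_equal(trimmed$step_width_cm$mean, full$step_width_cm$mean)
  expect_equal(trimmed$cadence_spm, full$cadence_spm)
})

test_that("mean step length times cadence is internally consistent with speed", {
  for (seed in c(61, 62)) {
    p <- grid_profile(seed, noise_cm = 0.3)
    g <- generate_trajectories(p)
    s <- spatiotemporal_summary(g$trial, detect_gait_events(g$trial))
    implied <- s$step_length_cm$mean / 100 * s$cadence_spm / 60
    expect_equal(implied, s$walking_speed_ms, tolerance = 0.1)
  }
})
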