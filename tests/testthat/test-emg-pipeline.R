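fs <- 1000
tt <- seq(0, 5, by = 1 / fs)

test_that("the notch stage removes powerline tones", {
  tone <- sin(2 * pi * 50 * tt)
  st <- emg_filter_chain(matrix(tone, dimnames = list(NULL, "TA_R")),
                         fs = fs, return_stages = TRUE)
  interior <- 1000:4000
  p_in <- mean(tone[interior]^2)
  p_out <- mean(st$notched[interior, 1]^2)
  expect_lt(p_out / p_in, 0.01)
})

test_that("the high-pass stage blocks sub-cutoff drift", {
  slow <- sin(2 * pi * 1 * tt)
  st <- emg_filter_chain(matrix(slow, dimnames = list(NULL, "TA_R")),
                         fs = fs, return_stages = TRUE)
  interior <- 1000:4000
  expect_lt(mean(st$highpass[interior, 1]^2) / mean(slow[interior]^2), 0.01)
})

test_that("rectification returns the amplitude of a pure tone", {
  x <- 3 * sin(2 * pi * 80 * tt)
  st <- emg_filter_chain(matrix(x, dimnames = list(NULL, "GAM_L")),
                         fs = fs, return_stages = TRUE)
  interior <- 1000:4000
  expect_equal(mean(st$rectified[interior, 1]), 3, tolerance = 0.01)
})

test_that("zero input gives zero output and outputs are non-negative", {
  env <- emg_filter_chain(matrix(0, 2000, 1, dimnames = list(NULL, "VL_L")),
                          fs = fs)
  expect_true(all(env == 0))
  set.seed(1)
  env2 <- emg_filter_chain(matrix(rnorm(5000), dimnames = list(NULL, "VL_L")),
                           fs = fs)
  expect_true(all(env2 >= 0))
})

test_that("the chain is zero-phase: reversal commutes with filtering", {
  set.seed(2)
  x <- rnorm(6000)
  m <- function(v) matrix(v, dimnames = list(NULL, "ST_R"))
  a <- emg_filter_chain(m(x), fs = fs)
  b <- rev(emg_filter_chain(m(rev(x)), fs = fs))
  expect_lt(max(abs(a - b)) / max(abs(a)), 1e-6)
})

test_that("too low a sampling rate for the notches is refused", {
  expect_error(emg_filter_chain(matrix(rnorm(1000),
                                       dimnames = list(NULL, "TA_R")),
                                fs = 400),
               "too low")
})

test_that("stride segmentation resamples contact-to-contact onto the normalized grid", {
  ev <- gait_events(left = list(contact = c(0.5, 1.5, 2.5), off = c(1.2, 2.2)),
                    right = list(contact = c(0, 1, 2, 3), off = c(0.7, 1.7, 2.7)),
                    source = "truth")
  x <- rep(2, 3001)                       # constant signal, 3 s at 1000 Hz
  m <- segment_strides(x, ev, "right", fs = 1000)
  expect_equal(dim(m), c(3, 101))
  expect_true(all(m == 2))
  m2 <- segment_strides(x, ev, "left", fs = 1000)
  expect_equal(nrow(m2), 2)               # 3 contacts -> 2 strides
  expect_error(segment_strides(x, gait_events(
    left = list(contact = 0.5, off = numeric()),
    right = list(contact = 0.2, off = numeric()), source = "truth"),
    "left", fs = 1000), "no complete stride")
})

test_that("a synthetic burst lands at its cycle phase in the stride matrix", {
  p <- gait_profile(noise_sd_emg = 0, powerline_amplitude = 0, seed = 23)
  g <- generate_trajectories(p)
  rec <- generate_emg(p, list(muscle_burst("SOL", "left", 0.30, 0.10)), g$events)
  m <- segment_strides(rec$truth_env[, "SOL_L"], g$events, "left",
                       fs = rec$sampling_rate)
  peaks <- apply(m, 1, which.max)
  frac <- (peaks - 1) / 100
  inner <- frac[rowSums(m) > 0]
  expect_true(all(inner >= 0.30 & inner <= 0.40))
})

test_that("artifact screening keeps identical strides and drops planted outliers", {
  base <- matrix(rep(sin(seq(0, pi, length.out = 101)), 6), 6, 101,
                 byrow = TRUE)
  none <- screen_artifacts(base)
  expect_equal(nrow(none$mat), 6)
  expect_equal(nrow(none$excluded), 0)
  # one stride multiplied by 100: leave-one-out z of its RMS is infinite
  # (the other strides are identical), so the z-rule must fire
  out <- base
  out[3, ] <- out[3, ] * 100
  sc <- screen_artifacts(out)
  expect_equal(sc$excluded$stride, 3)
  expect_equal(sc$excluded$reason, "amplitude_outlier")
  # manual exclusion wins regardless of the rules
  man <- screen_artifacts(base, manual_exclude = 2)
  expect_true(2 %in% man$excluded$stride)
  expect_equal(man$excluded$reason[man$excluded$stride == 2], "manual")
  # flatline rule
  flat <- base
  flat[4, ] <- 0.5
  expect_true("flatline" %in% screen_artifacts(flat)$excluded$reason)
  # everything excluded is an error
  expect_error(screen_artifacts(base, manual_exclude = 1:6), "no usable strides")
})

test_that("peak normalization scales the muscle maximum to exactly one", {
  m <- matrix(c(1, 2, 0.5, 4), 2, 2)
  n1 <- peak_normalize(m)
  expect_equal(max(n1), 1)
  expect_equal(n1, m / 4)
  expect_equal(peak_normalize(n1), n1)    # idempotent
  two <- rbind(2 * sin(seq(0, pi, length.out = 101)),
               4 * sin(seq(0, pi, length.out = 101)))
  n2 <- peak_normalize(two)
  expect_equal(apply(n2, 1, max), c(0.5, 1.0))
  expect_error(peak_normalize(matrix(0, 2, 5)), "silent channel")
})

test_that("the stimulated/non-stimulated ratio follows its defining arithmetic", {
  frac <- seq(0, 1, length.out = 101)
  expect_equal(stim_ratio(rep(1, 101), c(0.1, 0.4))$ratio, 1)
  env <- ifelse(frac >= 0.1 & frac <= 0.4, 0.8, 0.2)
  r <- stim_ratio(env, c(0.1, 0.4))
  expect_equal(r$ratio, 4, tolerance = 1e-12)
  expect_equal(r$mean_stim, 0.8)
  expect_equal(r$mean_nonstim, 0.2)
  expect_false(r$denominator_guarded)
  # zero outside the window triggers the epsilon guard
  env0 <- ifelse(frac >= 0.1 & frac <= 0.4, 0.8, 0)
  g <- stim_ratio(env0, c(0.1, 0.4))
  expect_true(g$denominator_guarded)
  expect_equal(g$ratio, 0.8 / 1e-6)
  expect_error(stim_ratio(env, c(0.5, 1.2)), "sub-intervals")
})

test_that("ratio changes across assessments difference against baseline with gaps", {
  r <- data.frame(muscle = "TA", side = "left",
                  assessment = c("baseline", "post", "followup"),
                  ratio = c(2, 3, 2.5))
  ch <- ratio_change(r)
  expect_equal(ch$change_post, 1)
  expect_equal(ch$change_followup, 0.5)
  same <- r
  same$ratio <- 2
  expect_true(all(unlist(ratio_change(same)[c("change_post", "change_followup")]) == 0))
  gap <- r[r$assessment != "post", ]
  chg <- ratio_change(gap)
  expect_true(is.na(chg$change_post))
  expect_equal(chg$change_followup, 0.5)
})

test_that("the processed envelope tracks the generator's ground truth on clean signals", {
  p <- gait_profile(noise_sd_emg = 0, powerline_amplitude = 0, seed = 4)
  trial <- synthetic_trial(p)
  env <- emg_filter_chain(trial$emg)
  for (lab in c("TA_R", "GAM_L", "ST_R")) {
    side <- if (grepl("_L$", lab)) "left" else "right"
    pr <- colMeans(segment_strides(env[, lab], trial$events_truth, side,
                                   fs = trial$emg$sampling_rate))
    tp <- colMeans(segment_strides(trial$emg$truth_env[, lab],
                                   trial$events_truth, side,
                                   fs = trial$emg$sampling_rate))
    expect_gt(stats::cor(pr, tp), 0.95)
  }
})
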