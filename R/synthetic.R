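# Synthetic gait generator.
#
# The trial is built in continuous time and then sampled. Construction:
#   * the spine base advances along +x (anterior) at the profile speed
#     plus a small step-periodic modulation (1 cm amplitude);
#   * each ankle's anterior-posterior (AP) position *relative to the
#     spine base* is a smooth periodic waveform with exactly one maximum
#     per stride (at foot contact) and one minimum (at foot off), made of
#     two half-cosine segments spanning stance and swing;
#   * a per-side constant AP offset (+/- asymmetry/4) makes consecutive
#     footfall locations differ by the left/right step lengths;
#   * mediolateral (ML, +y leftward) ankle positions sit at +/- half the
#     step width; vertical (z) has a swing-phase clearance bump.
# Ground-truth events are the exact construction times; ground-truth
# footfalls are medians of the noiseless construction over the true
# single-support windows, i.e. the quantity the spatiotemporal stage
# estimates.

# Periodic relative-AP waveform: phase in [0,1), +1 at contact (phase 0),
# -1 at foot off (phase = stance fraction).
rel_ap_wave <- function(phase, stance_fraction) {
  stance <- phase <= stance_fraction
  out <- numeric(length(phase))
  out[stance] <- cos(pi * phase[stance] / stance_fraction)
  out[!stance] <- -cos(pi * (phase[!stance] - stance_fraction) /
                         (1 - stance_fraction))
  out
}

#' Generate synthetic walking trajectories with ground-truth events
#'
#' Emulates a markerless motion-capture recording of one walkway pass:
#' time-stamped 3D positions of the left ankle, right ankle and spine
#' base, plus the exact foot-contact and foot-off times used in the
#' construction.
#'
#' The generator requires `stance_fraction > 0.5` (overground walking has
#' double-support phases; smaller values would imply flight).
#'
#' @param profile A [gait_profile()].
#' @return A list with elements `trial` (a `trajectory_trial`) and
#'   `events` (a `gait_events` with `source = "truth"`). The trial also
#'   carries the noiseless relative-AP signals (`rel_truth`) and the
#'   ground-truth footfall locations (`footfalls`).
#' @examples
#' g <- generate_trajectories(gait_profile(seed = 1))
#' range(g$trial$points$spine_base$x)
#' @export
generate_trajectories <- function(profile) {
  stopifnot(inherits(profile, "gait_profile"))
  if (profile$stance_fraction <= 0.5)
    stopf(paste0("stance_fraction %.2f <= 0.5 implies a flight phase; ",
                 "the walking generator requires double support"),
          profile$stance_fraction)
  set.seed(profile$seed)

  v <- profile$walking_speed
  stride_t <- 120 / profile$cadence            # s per stride (2 steps)
  step_t <- 60 / profile$cadence
  sf <- profile$stance_fraction
  fs <- profile$trajectory_rate
  x0 <- -0.5                                   # start 0.5 m before the 0 m line
  duration <- (profile$walkway_length + 1) / v
  t <- seq(0, duration, by = 1 / fs)
  n <- length(t)

  mod_amp <- 0.01                              # within-stride speed modulation, m
  spine_x <- x0 + v * t + mod_amp * sin(2 * pi * t / step_t)

  step_m <- profile$step_length_mean / 100
  asym_m <- profile$step_length_asymmetry / 100
  amp <- c(left = (step_m - asym_m / 2) / 2, right = (step_m + asym_m / 2) / 2)
  offset <- c(left = -asym_m / 4, right = asym_m / 4)
  width_m <- profile$step_width_mean / 100
  ml <- c(left = width_m / 2, right = -width_m / 2)
  phase0 <- c(left = step_t, right = 0)        # first right contact at t = 0

  events <- list()
  rel <- list()
  pts <- list()
  for (side in SIDES) {
    contacts <- seq(phase0[[side]], duration, by = stride_t)
    offs <- contacts + sf * stride_t
    offs <- offs[offs <= duration]
    events[[side]] <- list(contact = contacts, off = offs)
    phase <- ((t - phase0[[side]]) %% stride_t) / stride_t
    rel[[side]] <- offset[[side]] + amp[[side]] * rel_ap_wave(phase, sf)
    z <- rep(0.08, n)
    swing <- phase > sf
    z[swing] <- 0.08 + 0.06 * sin(pi * (phase[swing] - sf) / (1 - sf))
    pts[[paste0("ankle_", side_suffix(side))]] <-
      data.frame(x = spine_x + rel[[side]], y = ml[[side]], z = z)
  }
  pts$spine_base <- data.frame(x = spine_x, y = 0, z = 0.95)

  truth <- gait_events(left = events$left, right = events$right,
                       source = "truth")

  # Ground-truth footfalls: median of the *noiseless* ankle position over
  # each true single-support window (same estimator the pipeline applies
  # to the sampled data).
  ff <- list()
  for (side in SIDES) {
    for (iv in single_support_intervals(truth, side)) {
      sel <- t >= iv[1] & t <= iv[2]
      if (!any(sel)) next
      p <- pts[[paste0("ankle_", side_suffix(side))]]
      ff[[length(ff) + 1L]] <- data.frame(
        side = side, t_start = iv[1], t_end = iv[2],
        t_mid = mean(iv),
        ap_cm = stats::median(p$x[sel]) * 100,
        ml_cm = stats::median(p$y[sel]) * 100)
    }
  }
  footfalls <- do.call(rbind, ff)
  footfalls <- footfalls[order(footfalls$t_mid), ]
  rownames(footfalls) <- NULL

  noise_m <- profile$noise_sd_trajectory / 100
  if (noise_m > 0)
    for (nm in names(pts))
      for (ax in c("x", "y", "z"))
        pts[[nm]][[ax]] <- pts[[nm]][[ax]] + stats::rnorm(n, 0, noise_m)

  trial <- trajectory_trial(time_s = t, points = pts, sampling_rate = fs,
                            walkway_length = profile$walkway_length)
  trial$rel_truth <- data.frame(time_s = t, left = rel$left, right = rel$right)
  trial$footfalls <- footfalls
  list(trial = trial, events = truth)
}

#' Generate synthetic multi-channel surface EMG
#'
#' Each channel is a sum over strides of a raised-cosine burst envelope at
#' the specified cycle phase, multiplied by a zero-mean broadband carrier,
#' plus powerline interference at 50 k Hz (k = 1..5, common random phase,
#' harmonic amplitudes scaled by 1/k) and additive white noise. The exact
#' burst envelope of every channel is retained for oracle tests.
#'
#' @param profile A [gait_profile()].
#' @param bursts List of [muscle_burst()] specifications.
#' @param events A `gait_events` object giving per-side foot contacts
#'   (typically the generator's ground truth).
#' @param duration Recording length in s; defaults to the span implied by
#'   the profile's walkway and speed.
#' @return An `emg_recording` with a `truth_env` matrix attached.
#' @export
generate_emg <- function(profile, bursts = default_bursts(), events,
                         duration = NULL) {
  stopifnot(inherits(profile, "gait_profile"), inherits(events, "gait_events"))
  if (length(bursts) == 0L) stopf("no burst specifications given")
  for (b in bursts)
    if (!inherits(b, "muscle_burst"))
      stopf("all elements of 'bursts' must be muscle_burst objects")
  set.seed(profile$seed + 1L)

  fs <- profile$emg_rate
  duration <- duration %||% ((profile$walkway_length + 1) / profile$walking_speed)
  # Round the sample count up to a 5-smooth number: the rectification
  # stage works in the frequency domain and mixed-radix FFTs degrade
  # badly on lengths with large prime factors.
  n <- stats::nextn(length(seq(0, duration, by = 1 / fs)), c(2, 3, 5))
  t <- (seq_len(n) - 1L) / fs

  labels <- vapply(bursts, function(b) channel_label(b$muscle, b$side), "")
  if (anyDuplicated(labels))
    stopf("duplicate burst channel(s): %s",
          paste(unique(labels[duplicated(labels)]), collapse = ", "))

  env <- matrix(0, n, length(labels), dimnames = list(NULL, labels))
  for (j in seq_along(bursts)) {
    b <- bursts[[j]]
    contacts <- events[[b$side]]$contact
    if (length(contacts) == 0L)
      stopf("no foot contacts for side '%s'", b$side)
    strides <- diff(contacts)
    med_t <- if (length(strides)) stats::median(strides) else duration
    for (i in seq_along(contacts)) {
      st <- if (i < length(contacts)) strides[i] else med_t
      t0 <- contacts[i] + b$burst_onset * st
      bd <- b$burst_duration * st
      sel <- t >= t0 & t <= t0 + bd
      if (!any(sel)) next
      u <- (t[sel] - t0) / bd
      env[sel, j] <- env[sel, j] + b$burst_amplitude * 0.5 * (1 - cos(2 * pi * u))
    }
  }

  sig <- env * matrix(stats::rnorm(n * ncol(env)), n)
  if (profile$powerline_amplitude > 0) {
    ph <- stats::runif(1, 0, 2 * pi)           # common phase per trial
    pl <- numeric(n)
    for (k in 1:5)
      pl <- pl + profile$powerline_amplitude / k * sin(2 * pi * 50 * k * t + ph)
    sig <- sig + pl
  }
  if (profile$noise_sd_emg > 0)
    sig <- sig + matrix(stats::rnorm(n * ncol(env), 0, profile$noise_sd_emg), n)

  emg_recording(signals = sig, sampling_rate = fs, truth_env = env)
}

#' Assemble a complete synthetic trial
#'
#' Generates trajectories with ground-truth events, EMG, and the realized
#' stimulation timeline of a schedule triggered by the true initial
#' contacts. All randomness derives from `profile$seed`.
#'
#' @param profile A [gait_profile()].
#' @param bursts Burst specifications for [generate_emg()].
#' @param schedule A `stim_schedule`; by default the standard gait-phase
#'   sequence for the profile's stance fraction and stride time.
#' @return A `synthetic_trial` list: `trajectories`, `events_truth`,
#'   `emg`, `stim_truth`, `schedule`, `profile`.
#' @examples
#' trial <- synthetic_trial(gait_profile(seed = 3))
#' names(trial)
#' @export
synthetic_trial <- function(profile, bursts = default_bursts(),
                            schedule = NULL) {
  g <- generate_trajectories(profile)
  schedule <- schedule %||%
    default_fes_schedule(profile$stance_fraction, 1000 * 120 / profile$cadence)
  emg <- generate_emg(profile, bursts, g$events)
  structure(list(trajectories = g$trial,
                 events_truth = g$events,
                 emg = emg,
                 stim_truth = realize_timeline(schedule, g$events),
                 schedule = schedule,
                 profile = profile),
            class = "synthetic_trial")
}
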