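#' Gait profile for the synthetic generator
#'
#' Defines the kinematic and signal conditions of one synthetic overground
#' walking trial. Speed, step length and cadence must be mutually
#' consistent: `walking_speed ~ step_length_mean/100 * cadence/60` within
#' `consistency_tol` (relative), otherwise the profile is rejected.
#'
#' @param walking_speed Forward speed in m/s.
#' @param step_length_mean Mean step length in cm.
#' @param step_length_asymmetry Right-minus-left step length difference in cm.
#' @param step_width_mean Mean step width in cm.
#' @param cadence Steps per minute (both feet pooled).
#' @param stance_fraction Stance time over stride time, in (0, 1).
#' @param trajectory_rate Motion-capture sampling rate in Hz.
#' @param emg_rate EMG sampling rate in Hz.
#' @param walkway_length Walkway length in m.
#' @param noise_sd_trajectory Per-axis Gaussian position noise SD in cm.
#' @param noise_sd_emg Additive white-noise SD on EMG channels
#'   (dimensionless analog units).
#' @param powerline_amplitude Amplitude of the 50 Hz interference
#'   fundamental (harmonics scale as 1/k).
#' @param seed Integer seed; identical profiles generate identical trials.
#' @param consistency_tol Relative tolerance of the speed consistency check.
#' @return An object of class `gait_profile`.
#' @examples
#' gait_profile(walking_speed = 1.0, step_length_mean = 50, cadence = 120)
#' @export
gait_profile <- function(walking_speed = 0.8,
                         step_length_mean = 50,
                         step_length_asymmetry = 0,
                         step_width_mean = 12,
                         cadence = 96,
                         stance_fraction = 0.62,
                         trajectory_rate = 30,
                         emg_rate = 1000,
                         walkway_length = 10,
                         noise_sd_trajectory = 0.3,
                         noise_sd_emg = 0.05,
                         powerline_amplitude = 0.1,
                         seed = 1L,
                         consistency_tol = 0.02) {
  assert_scalar_num(walking_speed, "walking_speed", 0, open_lower = TRUE)
  assert_scalar_num(step_length_mean, "step_length_mean", 0, open_lower = TRUE)
  assert_scalar_num(step_length_asymmetry, "step_length_asymmetry")
  assert_scalar_num(step_width_mean, "step_width_mean", 0)
  assert_scalar_num(cadence, "cadence", 0, open_lower = TRUE)
  assert_scalar_num(stance_fraction, "stance_fraction", 0, 1,
                    open_lower = TRUE, open_upper = TRUE)
  assert_scalar_num(trajectory_rate, "trajectory_rate", 0, open_lower = TRUE)
  assert_scalar_num(emg_rate, "emg_rate", 0, open_lower = TRUE)
  assert_scalar_num(walkway_length, "walkway_length", 0, open_lower = TRUE)
  assert_scalar_num(noise_sd_trajectory, "noise_sd_trajectory", 0)
  assert_scalar_num(noise_sd_emg, "noise_sd_emg", 0)
  assert_scalar_num(powerline_amplitude, "powerline_amplitude", 0)
  implied <- step_length_mean / 100 * cadence / 60
  if (abs(implied - walking_speed) > consistency_tol * walking_speed)
    stopf(paste0("inconsistent profile: step_length_mean x cadence implies ",
                 "%.3f m/s but walking_speed is %.3f m/s ",
                 "(relative tolerance %.3g)"),
          implied, walking_speed, consistency_tol)
  structure(list(walking_speed = walking_speed,
                 step_length_mean = step_length_mean,
                 step_length_asymmetry = step_length_asymmetry,
                 step_width_mean = step_width_mean,
                 cadence = cadence,
                 stance_fraction = stance_fraction,
                 trajectory_rate = trajectory_rate,
                 emg_rate = emg_rate,
                 walkway_length = walkway_length,
                 noise_sd_trajectory = noise_sd_trajectory,
                 noise_sd_emg = noise_sd_emg,
                 powerline_amplitude = powerline_amplitude,
                 seed = as.integer(seed),
                 consistency_tol = consistency_tol),
            class = "gait_profile")
}

#' @export
print.gait_profile <- function(x, ...) {
  cat(sprintf(paste0("<gait_profile> %.2f m/s, step %.1f cm ",
                     "(asym %.1f), width %.1f cm, cadence %.0f spm, ",
                     "stance %.2f, seed %d\n"),
              x$walking_speed, x$step_length_mean, x$step_length_asymmetry,
              x$step_width_mean, x$cadence, x$stance_fraction, x$seed))
  invisible(x)
}

#' Muscle burst specification for synthetic EMG
#'
#' One gait-phase-locked activation burst: a raised-cosine envelope placed
#' at a fixed fraction of each gait cycle of the given side.
#'
#' @param muscle One of TA, GAM, SOL, PL, RF, VL, ST.
#' @param side `"left"` or `"right"`.
#' @param burst_onset Burst onset as a fraction of the gait cycle, in `[0, 1)`.
#' @param burst_duration Burst duration as a fraction of the cycle, in `(0, 1]`.
#'   Bursts whose onset + duration exceeds 1 wrap into the next cycle.
#' @param burst_amplitude Peak envelope amplitude (dimensionless, >= 0).
#' @return An object of class `muscle_burst`.
#' @export
muscle_burst <- function(muscle, side, burst_onset, burst_duration,
                         burst_amplitude = 1) {
  if (!muscle %in% EMG_MUSCLES)
    stopf("unknown muscle label '%s' (supported: %s)", muscle,
          paste(EMG_MUSCLES, collapse = ", "))
  side <- match.arg(side, SIDES)
  assert_scalar_num(burst_onset, "burst_onset", 0, 1, open_upper = TRUE)
  assert_scalar_num(burst_duration, "burst_duration", 0, 1, open_lower = TRUE)
  assert_scalar_num(burst_amplitude, "burst_amplitude", 0)
  structure(list(muscle = muscle, side = side, burst_onset = burst_onset,
                 burst_duration = burst_duration,
                 burst_amplitude = burst_amplitude),
            class = "muscle_burst")
}

#' Default burst set: one physiologically placed burst per muscle and side
#'
#' Burst phases follow textbook envelope timing for level walking:
#' plantarflexors in late stance (push-off), tibialis anterior and
#' peroneus longus in swing through loading, quadriceps around loading
#' response and late swing, semitendinosus in terminal swing.
#'
#' @param amplitude Common peak amplitude.
#' @return List of [muscle_burst()] objects covering all 14 channels.
#' @export
default_bursts <- function(amplitude = 1) {
  phase <- list(TA  = c(0.60, 0.35),
                GAM = c(0.30, 0.25),
                SOL = c(0.25, 0.30),
                PL  = c(0.20, 0.35),
                RF  = c(0.55, 0.30),
                VL  = c(0.00, 0.20),
                ST  = c(0.75, 0.25))
  out <- list()
  for (side in SIDES)
    for (m in names(phase))
      out[[channel_label(m, side)]] <-
        muscle_burst(m, side, phase[[m]][1], phase[[m]][2], amplitude)
  out
}
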