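# Multi-channel FES scheduling: per-channel onset/duration specs relative
# to ipsilateral initial contact, realized as on/off timelines that
# restart at each initial contact of the stimulated leg.

#' Stimulation channel specification
#'
#' @param muscle One of quadriceps, hamstrings, gluteii,
#'   tibialis_anterior, gastrocnemius.
#' @param side `"left"` or `"right"`.
#' @param onset_ms Onset in ms after ipsilateral initial contact (>= 0).
#' @param duration_ms Stimulation duration in ms (> 0).
#' @param frequency_hz Pulse frequency in Hz.
#' @param pulse_width_us Pulse width in microseconds, within `[1, 320]`.
#' @param intensity_note Free-text note on the per-participant intensity.
#' @return An object of class `stim_channel_spec`.
#' @export
stim_channel_spec <- function(muscle, side, onset_ms, duration_ms,
                              frequency_hz = 50, pulse_width_us = 100,
                              intensity_note = "") {
  if (!muscle %in% FES_MUSCLES)
    stopf("unknown FES muscle '%s' (supported: %s)", muscle,
          paste(FES_MUSCLES, collapse = ", "))
  side <- match.arg(side, SIDES)
  assert_scalar_num(onset_ms, "onset_ms", 0)
  assert_scalar_num(duration_ms, "duration_ms", 0, open_lower = TRUE)
  assert_scalar_num(frequency_hz, "frequency_hz", 0, open_lower = TRUE)
  assert_scalar_num(pulse_width_us, "pulse_width_us", 1, 320)
  structure(list(muscle = muscle, side = side, onset_ms = onset_ms,
                 duration_ms = duration_ms, frequency_hz = frequency_hz,
                 pulse_width_us = pulse_width_us,
                 intensity_note = intensity_note),
            class = "stim_channel_spec")
}

#' Stimulation schedule
#'
#' @param channels List of [stim_channel_spec()] objects, at most one per
#'   (muscle, side).
#' @param cycle_duration_ms Nominal stride time in ms, used to express
#'   channel windows as gait-cycle fractions.
#' @return An object of class `stim_schedule`.
#' @export
stim_schedule <- function(channels, cycle_duration_ms) {
  assert_scalar_num(cycle_duration_ms, "cycle_duration_ms", 0, open_lower = TRUE)
  for (ch in channels)
    if (!inherits(ch, "stim_channel_spec"))
      stopf("all channels must be stim_channel_spec objects")
  keys <- vapply(channels, function(ch) paste(ch$muscle, ch$side), "")
  if (anyDuplicated(keys))
    stopf("duplicate channel(s): %s", paste(unique(keys[duplicated(keys)]), collapse = ", "))
  names(channels) <- vapply(channels, function(ch) paste0(ch$muscle, "_", side_suffix(ch$side)), "")
  structure(list(channels = channels, cycle_duration_ms = cycle_duration_ms),
            class = "stim_schedule")
}

#' Default gait-phase stimulation schedule
#'
#' Places, bilaterally: gastrocnemius over the stance phase (propulsion),
#' tibialis anterior in early swing (foot clearance), quadriceps in mid
#' swing (knee extension), and hamstrings plus gluteii in terminal swing
#' (leg stabilisation before landing). Sub-phase boundaries split the
#' swing at configurable fractions (defaults: early swing ends at 40% of
#' swing, mid swing at 75%); all onsets/durations derive from
#' `stance_fraction * cycle_duration_ms`.
#'
#' @param stance_fraction Stance time over stride time, in (0, 1).
#' @param cycle_duration_ms Nominal stride time in ms.
#' @param swing_breaks Fractions of the swing phase ending early and mid
#'   swing.
#' @return A [stim_schedule()].
#' @examples
#' sch <- default_fes_schedule(0.6, 1200)
#' sch$channels$gastrocnemius_R[c("onset_ms", "duration_ms")]
#' @export
default_fes_schedule <- function(stance_fraction, cycle_duration_ms,
                                 swing_breaks = c(early = 0.4, mid = 0.75)) {
  assert_scalar_num(stance_fraction, "stance_fraction", 0, 1,
                    open_lower = TRUE, open_upper = TRUE)
  sf <- stance_fraction
  C <- cycle_duration_ms
  b1 <- (sf + swing_breaks[["early"]] * (1 - sf)) * C
  b2 <- (sf + swing_breaks[["mid"]] * (1 - sf)) * C
  windows <- list(gastrocnemius = c(0, sf * C),
                  tibialis_anterior = c(sf * C, b1),
                  quadriceps = c(b1, b2),
                  hamstrings = c(b2, C),
                  gluteii = c(b2, C))
  channels <- list()
  for (side in SIDES)
    for (m in names(windows)) {
      w <- windows[[m]]
      channels[[length(channels) + 1L]] <-
        stim_channel_spec(m, side, onset_ms = w[1], duration_ms = w[2] - w[1])
    }
  stim_schedule(channels, cycle_duration_ms)
}

#' Realize a schedule as an event-driven stimulation timeline
#'
#' For each ipsilateral initial contact `c`, a channel turns on at
#' `c + onset` and off at `c + onset + duration`, truncated when the
#' restarted window of the next ipsilateral contact begins (the restart
#' takes precedence). Pending windows after the last contact run to
#' completion. Sides with no contacts yield an empty timeline with a
#' warning.
#'
#' @param schedule A [stim_schedule()].
#' @param events A [gait_events()] object.
#' @return A `stim_timeline`: per channel, a matrix with columns
#'   `start_s`, `end_s` of non-overlapping on-intervals.
#' @examples
#' ev <- gait_events(left = list(contact = numeric(), off = numeric()),
#'                   right = list(contact = c(0, 1.2, 2.4), off = c(0.8, 2.0)))
#' sch <- stim_schedule(list(stim_channel_spec("quadriceps", "right", 100, 300)), 1200)
#' realize_timeline(sch, ev)$intervals
#' @export
realize_timeline <- function(schedule, events) {
  stopifnot(inherits(schedule, "stim_schedule"), inherits(events, "gait_events"))
  out <- list()
  for (nm in names(schedule$channels)) {
    ch <- schedule$channels[[nm]]
    contacts <- events[[ch$side]]$contact
    if (length(contacts) == 0L) {
      warning(sprintf("no %s-side contacts: channel %s has an empty timeline",
                      ch$side, nm), call. = FALSE)
      out[[nm]] <- matrix(numeric(), 0, 2,
                          dimnames = list(NULL, c("start_s", "end_s")))
      next
    }
    onset <- ch$onset_ms / 1000
    dur <- ch$duration_ms / 1000
    start <- contacts + onset
    end <- start + dur
    if (length(contacts) > 1L) {
      restart <- c(start[-1], Inf)
      end <- pmin(end, restart)
    }
    keep <- end > start
    out[[nm]] <- cbind(start_s = start[keep], end_s = end[keep])
  }
  structure(list(intervals = out, schedule = schedule), class = "stim_timeline")
}

#' @export
print.stim_timeline <- function(x, ...) {
  n <- vapply(x$intervals, nrow, 0L)
  cat(sprintf("<stim_timeline> %d channels, %d on-intervals total\n",
              length(n), sum(n)))
  invisible(x)
}

#' Gait-cycle window of a channel
#'
#' The channel's `[onset, onset + duration]`, expressed as fractions of
#' the schedule's nominal cycle, clipped to `[0, 1)` and split in two if
#' it wraps past the end of the cycle.
#'
#' @param schedule A [stim_schedule()].
#' @param muscle,side Channel identifier.
#' @return Matrix with columns `start`, `end` (one or two rows).
#' @export
cycle_window <- function(schedule, muscle, side) {
  stopifnot(inherits(schedule, "stim_schedule"))
  side <- match.arg(side, SIDES)
  nm <- paste0(muscle, "_", side_suffix(side))
  ch <- schedule$channels[[nm]]
  if (is.null(ch)) stopf("no channel '%s' in schedule", nm)
  C <- schedule$cycle_duration_ms
  if (ch$duration_ms >= C)
    return(cbind(start = 0, end = 1))
  a <- (ch$onset_ms %% C) / C
  b <- a + ch$duration_ms / C
  if (b <= 1) cbind(start = a, end = b)
  else cbind(start = c(a, 0), end = c(1, b - 1))
}

#' Calibrate stimulation intensity bounds from a recruitment curve
#'
#' Given a non-decreasing muscle response over pulse width, returns the
#' smallest pulse width whose response reaches the motor threshold and
#' the largest whose response stays at or below the maximum tolerated
#' level.
#'
#' @param recruitment A function of pulse width (microseconds), or a data
#'   frame with columns `pulse_width_us` and `response` interpolated
#'   linearly.
#' @param motor_threshold_level Response at the motor threshold (visible
#'   contraction).
#' @param max_level Maximum tolerated response.
#' @param grid Pulse widths (microseconds) evaluated, within `[1, 320]`.
#' @return Named numeric `c(min_pulse_width_us, max_pulse_width_us)`.
#' @examples
#' calibrate_intensity(function(w) w / 320, 0.25, 0.75)  # c(80, 240)
#' @export
calibrate_intensity <- function(recruitment, motor_threshold_level, max_level,
                                grid = 1:320) {
  if (any(grid < 1) || any(grid > 320))
    stopf("pulse-width grid must lie within [1, 320] microseconds")
  r <- if (is.function(recruitment)) {
    vapply(grid, recruitment, 0)
  } else {
    rd <- as.data.frame(recruitment)
    if (!all(c("pulse_width_us", "response") %in% names(rd)))
      stopf("recruitment table needs columns pulse_width_us and response")
    stats::approx(rd$pulse_width_us, rd$response, xout = grid, rule = 2)$y
  }
  if (any(diff(r) < -1e-9)) stopf("recruitment curve must be non-decreasing")
  i_min <- which(r >= motor_threshold_level)
  if (!length(i_min))
    stopf("muscle not stimulable: motor threshold not reached within 320 microseconds")
  i_max <- which(r <= max_level)
  if (!length(i_max) || max(grid[i_max]) < grid[i_min[1]])
    stopf("no pulse width satisfies both the motor threshold and the maximum level")
  c(min_pulse_width_us = grid[i_min[1]], max_pulse_width_us = max(grid[i_max]))
}
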