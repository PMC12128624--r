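# Spatiotemporal gait parameters from trajectories and events, restricted
# to the 2-8 m walkway window to avoid acceleration/deceleration effects.

#' Step locations
#'
#' One location per single-support interval: the component-wise median of
#' that ankle's AP and ML positions over the interval, in cm. Empty
#' intervals (no samples after windowing) are skipped with a message.
#'
#' @param trial A [trajectory_trial()].
#' @param events A [gait_events()] object.
#' @return Data frame with columns `side`, `t_start`, `t_end`, `t_mid`,
#'   `ap_cm`, `ml_cm`, ordered in time.
#' @export
step_locations <- function(trial, events) {
  stopifnot(inherits(trial, "trajectory_trial"), inherits(events, "gait_events"))
  t <- trial$time_s
  rows <- list()
  for (side in SIDES) {
    ivs <- single_support_intervals(events, side)
    p <- trial$points[[paste0("ankle_", side_suffix(side))]]
    for (iv in ivs) {
      sel <- t >= iv[1] & t <= iv[2]
      if (!any(sel)) {
        message(sprintf("step_locations: empty single-support interval [%.3f, %.3f] s (%s) skipped",
                        iv[1], iv[2], side))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        side = side, t_start = iv[1], t_end = iv[2], t_mid = mean(iv),
        ap_cm = stats::median(p$x[sel]) * 100,
        ml_cm = stats::median(p$y[sel]) * 100)
    }
  }
  if (!length(rows)) stopf("no step locations: no usable single-support intervals")
  out <- do.call(rbind, rows)
  out <- out[order(out$t_mid), ]
  rownames(out) <- NULL
  out
}

#' Step lengths and widths from consecutive step locations
#'
#' For each consecutive pair of alternating-side locations: step length is
#' the signed AP difference (negative values, i.e. backward steps, are
#' flagged, not clamped) and step width the absolute ML difference, both
#' in cm. Consecutive locations from the same side are skipped with a
#' message.
#'
#' @param locations Data frame as returned by [step_locations()],
#'   ordered in time.
#' @return Data frame with columns `side` (the stepping foot), `t_mid`,
#'   `length_cm`, `width_cm`, `backward`.
#' @export
step_length_width <- function(locations) {
  if (nrow(locations) < 2L)
    stopf("need at least 2 step locations, got %d", nrow(locations))
  rows <- list()
  for (k in seq_len(nrow(locations) - 1L)) {
    a <- locations[k, ]; b <- locations[k + 1L, ]
    if (a$side == b$side) {
      message(sprintf("step_length_width: consecutive %s-side locations at %.3f and %.3f s skipped",
                      a$side, a$t_mid, b$t_mid))
      next
    }
    len <- b$ap_cm - a$ap_cm
    rows[[length(rows) + 1L]] <- data.frame(
      side = b$side, t_mid = b$t_mid, length_cm = len,
      width_cm = abs(b$ml_cm - a$ml_cm), backward = len < 0)
  }
  if (!length(rows)) stopf("no valid alternating-side step pairs")
  out <- do.call(rbind, rows)
  if (any(out$backward))
    message(sprintf("step_length_width: %d backward step(s) flagged", sum(out$backward)))
  rownames(out) <- NULL
  out
}

#' Cadence from pooled foot contacts
#'
#' `(n_contacts - 1) / (t_last - t_first) * 60` over the supplied contact
#' times (both feet pooled).
#'
#' @param contact_times Numeric vector of foot-contact times in s.
#' @return Cadence in steps/min.
#' @examples
#' st_cadence(seq(0, 6, by = 0.6))  # 11 contacts over 6 s -> 100
#' @export
st_cadence <- function(contact_times) {
  contact_times <- sort(contact_times)
  if (length(contact_times) < 2L)
    stopf("cadence needs >= 2 foot contacts, got %d", length(contact_times))
  span <- contact_times[length(contact_times)] - contact_times[1]
  if (span <= 0) stopf("contact times span zero duration")
  (length(contact_times) - 1) / span * 60
}

#' Walking speed over the measurement window
#'
#' The window width divided by the time between linearly interpolated
#' crossings of the window lines by the spine-base AP position.
#'
#' @param trial A [trajectory_trial()].
#' @param window Numeric `c(start, end)` in m; default 2-8 m.
#' @return Speed in m/s.
#' @export
walking_speed <- function(trial, window = c(2, 8)) {
  stopifnot(inherits(trial, "trajectory_trial"))
  x <- trial$points$spine_base$x
  t1 <- first_crossing(trial$time_s, x, window[1])
  t2 <- first_crossing(trial$time_s, x, window[2])
  if (is.na(t1) || is.na(t2) || t2 <= t1)
    stopf("walkway not fully traversed: spine base does not cross both the %g m and %g m lines",
          window[1], window[2])
  (window[2] - window[1]) / (t2 - t1)
}

#' Spatiotemporal summary of one walkway pass
#'
#' Assembles walking speed, per-step lengths and widths, cadence and step
#' count, restricted to the measurement window: a step belongs to the
#' window if its later step location's AP position lies in
#' `[window[1], window[2])` m (half-open at the far line), and cadence
#' uses the pooled contacts between the spine base's crossings of the two
#' window lines.
#'
#' @param trial A [trajectory_trial()].
#' @param events A [gait_events()] object.
#' @param window Numeric `c(start, end)` in m.
#' @return An object of class `spatiotemporal_summary`.
#' @export
spatiotemporal_summary <- function(trial, events, window = c(2, 8)) {
  locs <- step_locations(trial, events)
  steps <- step_length_width(locs)
  later_ap <- locs$ap_cm[match(steps$t_mid, locs$t_mid)]
  keep <- later_ap >= window[1] * 100 & later_ap < window[2] * 100
  steps <- steps[keep, ]
  if (nrow(steps) < 1L) stopf("no steps inside the %g-%g m window", window[1], window[2])

  x <- trial$points$spine_base$x
  t1 <- first_crossing(trial$time_s, x, window[1])
  t2 <- first_crossing(trial$time_s, x, window[2])
  pooled <- sort(c(events$left$contact, events$right$contact))
  pooled <- pooled[pooled >= t1 & pooled <= t2]
  structure(list(
    walking_speed_ms = walking_speed(trial, window),
    step_length_cm = list(values = steps$length_cm, mean = mean(steps$length_cm)),
    step_width_cm = list(values = steps$width_cm, mean = mean(steps$width_cm)),
    cadence_spm = st_cadence(pooled),
    n_steps = nrow(steps),
    steps = steps,
    window = window), class = "spatiotemporal_summary")
}

#' @export
print.spatiotemporal_summary <- function(x, ...) {
  cat(sprintf(paste0("<spatiotemporal_summary> speed %.3f m/s, step length ",
                     "%.1f cm, step width %.1f cm, cadence %.1f spm ",
                     "(%d steps in the %g-%g m window)\n"),
              x$walking_speed_ms, x$step_length_cm$mean, x$step_width_cm$mean,
              x$cadence_spm, x$n_steps, x$window[1], x$window[2]))
  invisible(x)
}

#' Signed change between two spatiotemporal summaries
#'
#' @param a Reference summary (e.g. baseline).
#' @param b Comparison summary.
#' @return Named list of `b - a` differences per parameter.
#' @export
spatiotemporal_diff <- function(a, b) {
  stopifnot(inherits(a, "spatiotemporal_summary"),
            inherits(b, "spatiotemporal_summary"))
  list(walking_speed_ms = b$walking_speed_ms - a$walking_speed_ms,
       step_length_cm = b$step_length_cm$mean - a$step_length_cm$mean,
       step_width_cm = b$step_width_cm$mean - a$step_width_cm$mean,
       cadence_spm = b$cadence_spm - a$cadence_spm)
}
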