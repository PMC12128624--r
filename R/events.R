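# Gait-event detection from markerless trajectories.
#
# Foot contacts are local maxima, and foot offs local minima, of each
# ankle's anterior-posterior trajectory relative to the spine base. The
# relative signal is pre-smoothed with a zero-lag low-pass, extrema are
# screened by prominence and minimum spacing, extrema near the recording
# boundaries are discarded, and the contact/off alternation is enforced.

#' Trajectory trial container
#'
#' @param time_s Strictly increasing, uniformly sampled time stamps in s.
#' @param points Named list of data frames with columns `x`, `y`, `z`
#'   (m): must contain `ankle_L`, `ankle_R`, `spine_base`. Axis
#'   convention: anterior = +x from the 0 m walkway line, ML = +y
#'   leftward, up = +z.
#' @param sampling_rate Sampling rate in Hz.
#' @param walkway_length Walkway length in m.
#' @return An object of class `trajectory_trial`.
#' @export
trajectory_trial <- function(time_s, points, sampling_rate,
                             walkway_length = 10) {
  need <- c("ankle_L", "ankle_R", "spine_base")
  missing_pts <- setdiff(need, names(points))
  if (length(missing_pts))
    stopf("missing body point(s): %s", paste(missing_pts, collapse = ", "))
  n <- length(time_s)
  if (n < 2L || any(diff(time_s) <= 0))
    stopf("time_s must be strictly increasing with >= 2 samples")
  dt <- diff(time_s)
  if (max(dt) - min(dt) > 1e-6 * mean(dt))
    stopf("time_s must be uniformly sampled")
  for (nm in need) {
    p <- points[[nm]]
    if (!all(c("x", "y", "z") %in% names(p)) || nrow(as.data.frame(p)) != n)
      stopf("point '%s' must have columns x, y, z with %d rows", nm, n)
    points[[nm]] <- as.data.frame(p)[c("x", "y", "z")]
  }
  structure(list(time_s = time_s, points = points,
                 sampling_rate = sampling_rate,
                 walkway_length = walkway_length),
            class = "trajectory_trial")
}

#' Anterior-posterior ankle trajectory relative to the spine base
#'
#' @param trial A [trajectory_trial()].
#' @param side `"left"` or `"right"`.
#' @return Numeric vector `ankle_AP(t) - spinebase_AP(t)` in m on the
#'   trial's time base.
#' @export
relative_ap <- function(trial, side) {
  stopifnot(inherits(trial, "trajectory_trial"))
  side <- match.arg(side, SIDES)
  ankle <- paste0("ankle_", side_suffix(side))
  trial$points[[ankle]]$x - trial$points$spine_base$x
}

# Local maxima with prominence and minimum-spacing screening. Plateau
# ties resolve to the earlier sample. Returns sorted indices.
find_peaks <- function(x, min_prominence, min_distance) {
  n <- length(x)
  if (n < 3L) return(integer())
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer())
  prom <- vapply(cand, function(p) {
    i <- p
    lmin <- x[p]
    while (i > 1L && x[i - 1L] <= x[p]) {
      i <- i - 1L
      if (x[i] < lmin) lmin <- x[i]
    }
    j <- p
    rmin <- x[p]
    while (j < n && x[j + 1L] <= x[p]) {
      j <- j + 1L
      if (x[j] < rmin) rmin <- x[j]
    }
    x[p] - max(lmin, rmin)
  }, 0)
  keep <- cand[prom >= min_prominence]
  if (!length(keep)) return(integer())
  ord <- keep[order(x[keep], decreasing = TRUE)]
  sel <- integer()
  for (p in ord)
    if (!length(sel) || all(abs(sel - p) >= min_distance))
      sel <- c(sel, p)
  sort(sel)
}

#' Event-detector configuration
#'
#' @param smooth_cutoff_hz Zero-lag low-pass cutoff applied to the
#'   relative AP signal before the extremum search.
#' @param min_prominence_cm Minimum extremum prominence in cm.
#' @param cadence_max_spm Cadence ceiling; the minimum interval between
#'   same-type extrema is `60 / (2 * cadence_max_spm)` s.
#' @param edge_half_strides Extrema within this many half-strides of the
#'   recording boundaries are discarded (incomplete strides bias the
#'   step metrics).
#' @param refine If `TRUE` (default), each extremum is refined to
#'   sub-frame resolution by cross-correlating its neighbourhood with the
#'   trial's own stride-averaged waveform; because the template shares
#'   the signal's filtering distortion, the alignment is unbiased, and
#'   noise averages over the whole stride instead of just the samples at
#'   the peak.
#' @param template_halfwidth,max_lag Template half-window and maximum
#'   alignment lag, as fractions of the stride.
#' @return A list of detector settings.
#' @export
event_config <- function(smooth_cutoff_hz = 6, min_prominence_cm = 5,
                         cadence_max_spm = 180, edge_half_strides = 1,
                         refine = TRUE, template_halfwidth = 0.45,
                         max_lag = 0.25) {
  list(smooth_cutoff_hz = smooth_cutoff_hz,
       min_prominence_cm = min_prominence_cm,
       cadence_max_spm = cadence_max_spm,
       edge_half_strides = edge_half_strides,
       refine = refine, template_halfwidth = template_halfwidth,
       max_lag = max_lag)
}

# Sub-frame extremum refinement by alignment against the stride-averaged
# waveform. Returns extremum times (s); extrema whose window leaves the
# recording keep their sample-resolution time.
refine_extrema <- function(sm, idx, t, fs, stride_est, config) {
  refined <- t[idx]
  hw <- round(config$template_halfwidth * stride_est * fs)
  lagmax <- max(2L, round(config$max_lag * stride_est * fs))
  n <- length(sm)
  ok <- idx[idx - hw - lagmax >= 1 & idx + hw + lagmax <= n]
  if (length(ok) < 2L || hw < 2L) return(refined)
  tpl <- rowMeans(vapply(ok, function(p) sm[(p - hw):(p + hw)],
                         numeric(2L * hw + 1L)))
  tpl <- tpl - mean(tpl)
  lags <- -lagmax:lagmax
  for (j in seq_along(idx)) {
    p <- idx[j]
    if (p - hw - lagmax < 1 || p + hw + lagmax > n) next
    cc <- vapply(lags, function(L) {
      w <- sm[(p + L - hw):(p + L + hw)]
      sum((w - mean(w)) * tpl)
    }, 0)
    k <- which.max(cc)
    off <- lags[k]
    if (k > 1L && k < length(lags)) {
      denom <- cc[k - 1] - 2 * cc[k] + cc[k + 1]
      d <- if (denom != 0) (cc[k - 1] - cc[k + 1]) / (2 * denom) else 0
      if (is.finite(d) && abs(d) <= 1) off <- off + d
    }
    refined[j] <- t[p] + off / fs
  }
  refined
}

#' Detect foot-contact and foot-off events
#'
#' Foot contacts are the screened local maxima, and foot offs the local
#' minima, of each side's smoothed relative AP trajectory. Unpaired
#' extrema at the trial edges are dropped so that contacts and offs
#' alternate (exactly one foot off between consecutive same-side
#' contacts).
#'
#' @param trial A [trajectory_trial()].
#' @param config Detector settings from [event_config()].
#' @return A `gait_events` object with `source = "estimated"`.
#' @export
detect_gait_events <- function(trial, config = event_config()) {
  stopifnot(inherits(trial, "trajectory_trial"))
  fs <- trial$sampling_rate
  t <- trial$time_s
  min_dist <- max(1L, ceiling(fs * 60 / (2 * config$cadence_max_spm)))
  prom <- config$min_prominence_cm / 100
  out <- list()
  for (side in SIDES) {
    rel <- relative_ap(trial, side)
    sm <- butter_zero_phase(rel, fs, config$smooth_cutoff_hz, "low")
    imax <- find_peaks(sm, prom, min_dist)
    imin <- find_peaks(-sm, prom, min_dist)
    if (length(imax) < 2L)
      stopf("insufficient strides: %d foot contact(s) detected on the %s side",
            length(imax), side)
    stride_est <- stats::median(diff(t[imax]))
    contacts <- t[imax]
    offs <- t[imin]
    if (isTRUE(config$refine)) {
      contacts <- refine_extrema(sm, imax, t, fs, stride_est, config)
      offs <- refine_extrema(-sm, imin, t, fs, stride_est, config)
    }
    # Edge policy: discard extrema within half a stride of the boundaries.
    margin <- config$edge_half_strides * stride_est / 2
    keep_max <- contacts >= t[1] + margin & contacts <= t[length(t)] - margin
    keep_min <- offs >= t[1] + margin & offs <= t[length(t)] - margin
    imax <- imax[keep_max]; contacts <- contacts[keep_max]
    imin <- imin[keep_min]; offs <- offs[keep_min]
    if (length(contacts) < 2L)
      stopf("insufficient strides on the %s side after edge trimming", side)
    # Alternation: one off per contact gap (deepest if several), edges dropped.
    kept <- numeric()
    for (i in seq_len(length(contacts) - 1L)) {
      inside <- which(offs > contacts[i] & offs < contacts[i + 1L])
      if (length(inside) == 0L)
        stopf(paste0("inconsistent event ordering on the %s side: no foot ",
                     "off between contacts at %.3f and %.3f s"),
              side, contacts[i], contacts[i + 1L])
      if (length(inside) > 1L) {
        vals <- sm[imin][inside]
        inside <- inside[which.min(vals)]
      }
      kept <- c(kept, offs[inside])
    }
    out[[side]] <- list(contact = contacts, off = kept)
  }
  gait_events(left = out$left, right = out$right, source = "estimated")
}

#' Gait-event set
#'
#' @param left,right Lists with numeric vectors `contact` and `off`
#'   (times in s).
#' @param source `"truth"` or `"estimated"`.
#' @return An object of class `gait_events`.
#' @export
gait_events <- function(left, right, source = c("estimated", "truth")) {
  source <- match.arg(source)
  ev <- list(left = left, right = right)
  for (side in SIDES) {
    e <- ev[[side]]
    if (!all(c("contact", "off") %in% names(e)))
      stopf("side '%s' must supply 'contact' and 'off' times", side)
    if (is.unsorted(e$contact, strictly = TRUE))
      stopf("foot contacts on the %s side must be strictly increasing", side)
    if (is.unsorted(e$off, strictly = TRUE))
      stopf("foot offs on the %s side must be strictly increasing", side)
  }
  structure(list(left = ev$left, right = ev$right, source = source),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events source=%s> left: %d contacts / %d offs; right: %d / %d\n",
              x$source, length(x$left$contact), length(x$left$off),
              length(x$right$contact), length(x$right$off)))
  invisible(x)
}

#' Single-support intervals of one side
#'
#' Intervals during which only the given side is on the ground: from a
#' contralateral foot off to the next contralateral foot contact, kept
#' only when the interval lies inside a stance phase of the given side.
#' Partial intervals at the trial end (no following contralateral
#' contact) are dropped.
#'
#' @param events A [gait_events()] object.
#' @param side Stance side, `"left"` or `"right"`.
#' @return List of numeric `c(start, end)` intervals in s, ordered and
#'   non-overlapping.
#' @export
single_support_intervals <- function(events, side) {
  stopifnot(inherits(events, "gait_events"))
  side <- match.arg(side, SIDES)
  contra <- setdiff(SIDES, side)
  ips <- events[[side]]
  opp <- events[[contra]]
  # Stance phases of the given side: contact to the next own foot off.
  stances <- list()
  for (c0 in ips$contact) {
    nxt <- opp$contact[opp$contact > c0]
    own_off <- ips$off[ips$off > c0]
    if (length(own_off)) stances[[length(stances) + 1L]] <- c(c0, own_off[1])
  }
  out <- list()
  for (o in opp$off) {
    nc <- opp$contact[opp$contact > o]
    if (!length(nc)) next                     # partial interval at trial end
    iv <- c(o, nc[1])
    if (iv[2] <= iv[1])
      stopf("inconsistent event ordering: contralateral contact at %.3f s not after foot off at %.3f s",
            iv[2], iv[1])
    inside <- any(vapply(stances, function(s) iv[1] >= s[1] - 1e-9 && iv[2] <= s[2] + 1e-9, NA))
    if (isTRUE(inside)) out[[length(out) + 1L]] <- iv
  }
  out
}
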