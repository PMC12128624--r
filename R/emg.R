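# Surface-EMG linear-envelope pipeline and the stimulated/non-stimulated
# activity-ratio statistic.

#' Multi-channel EMG recording container
#'
#' @param signals Numeric matrix, samples x channels; column names are
#'   channel labels `<MUSCLE>_<L|R>` drawn from the supported muscle set.
#' @param sampling_rate Sampling rate in Hz.
#' @param truth_env Optional matrix of ground-truth burst envelopes (same
#'   shape), retained by the synthetic generator for oracle tests.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(signals, sampling_rate, truth_env = NULL) {
  signals <- as.matrix(signals)
  labs <- colnames(signals)
  if (is.null(labs) || anyDuplicated(labs))
    stopf("channel labels must be present and unique")
  valid <- as.vector(outer(EMG_MUSCLES, c("L", "R"), paste, sep = "_"))
  bad <- setdiff(labs, valid)
  if (length(bad))
    stopf("unknown channel label(s): %s", paste(bad, collapse = ", "))
  structure(list(signals = signals, sampling_rate = sampling_rate,
                 truth_env = truth_env),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channels x %d samples at %g Hz\n",
              ncol(x$signals), nrow(x$signals), x$sampling_rate))
  invisible(x)
}

emg_time <- function(rec) (seq_len(nrow(rec$signals)) - 1L) / rec$sampling_rate

#' EMG processing chain
#'
#' Applies, in order: zero-phase Butterworth high-pass; zero-phase
#' band-stop notches at the powerline harmonics; rectification as the
#' modulus of the analytic signal; zero-phase Butterworth low-pass. Small
#' negative values produced by low-pass ringing are clamped to zero (the
#' clamped count is attached as attribute `n_clamped`).
#'
#' @param rec An [emg_recording()] (or a plain numeric matrix/vector, in
#'   which case `fs` must be given).
#' @param spec An [emg_filter_spec()].
#' @param fs Sampling rate in Hz when `rec` is not an `emg_recording`.
#' @param return_stages If `TRUE`, return a list with each intermediate
#'   stage (`highpass`, `notched`, `rectified`, `envelope`) so stage-wise
#'   frequency responses can be measured.
#' @return Matrix of processed envelopes (samples x channels), or the
#'   stage list.
#' @export
emg_filter_chain <- function(rec, spec = emg_filter_spec(), fs = NULL,
                             return_stages = FALSE) {
  if (inherits(rec, "emg_recording")) {
    x <- rec$signals
    fs <- rec$sampling_rate
  } else {
    if (is.null(fs)) stopf("'fs' is required when 'rec' is a plain matrix")
    x <- as.matrix(rec)
  }
  f_max <- max(spec$notch_harmonics) * spec$notch_base_hz
  if (fs <= 2 * f_max)
    stopf("sampling rate %g Hz too low for a notch at %g Hz", fs, f_max)

  hp <- apply(x, 2, butter_zero_phase, fs = fs,
              cutoff_hz = spec$highpass_hz, type = "high", order = spec$order)
  nt <- hp
  half_bw <- spec$notch_bandwidth_hz / 2
  for (k in spec$notch_harmonics) {
    f0 <- k * spec$notch_base_hz
    nt <- apply(nt, 2, butter_zero_phase, fs = fs,
                cutoff_hz = c(f0 - half_bw, f0 + half_bw), type = "stop",
                order = spec$order / 2)  # band-stop doubles the order
  }
  rect <- apply(nt, 2, analytic_modulus)
  env <- apply(rect, 2, butter_zero_phase, fs = fs,
               cutoff_hz = spec$lowpass_hz, type = "low", order = spec$order)
  n_clamped <- sum(env < 0)
  env[env < 0] <- 0
  colnames(env) <- colnames(x)
  attr(env, "n_clamped") <- n_clamped
  if (return_stages)
    list(highpass = hp, notched = nt, rectified = rect, envelope = env)
  else env
}

#' Segment a processed signal into time-normalized strides
#'
#' Strides run from one foot contact to the next contact of the same
#' side; each is resampled by linear interpolation onto a fixed grid of
#' `n_points` spanning 0-100% of the gait cycle. Incomplete strides at
#' the recording edges are excluded.
#'
#' @param x Numeric vector (one channel) sampled at `fs` Hz from time 0.
#' @param events A [gait_events()] object.
#' @param side Which side's contacts delimit the strides.
#' @param fs Sampling rate in Hz.
#' @param n_points Number of grid points over the normalized cycle.
#' @return Matrix `n_strides x n_points`; attribute `stride_times` holds
#'   the contact times delimiting each stride.
#' @export
segment_strides <- function(x, events, side, fs, n_points = 101) {
  stopifnot(inherits(events, "gait_events"))
  side <- match.arg(side, SIDES)
  t <- (seq_along(x) - 1L) / fs
  contacts <- events[[side]]$contact
  contacts <- contacts[contacts >= t[1] - 1e-9 & contacts <= t[length(t)] + 1e-9]
  if (length(contacts) < 2L)
    stopf("no complete stride: %d foot contact(s) within the recording", length(contacts))
  grid <- seq(0, 1, length.out = n_points)
  out <- matrix(NA_real_, length(contacts) - 1L, n_points)
  for (i in seq_len(length(contacts) - 1L)) {
    tt <- contacts[i] + grid * (contacts[i + 1L] - contacts[i])
    out[i, ] <- stats::approx(t, x, xout = tt, rule = 2)$y
  }
  attr(out, "stride_times") <- contacts
  out
}

#' Artifact-screening rules
#'
#' Automated surrogate for visual artefact inspection.
#'
#' @param flatline_var Strides whose variance falls below this are
#'   flagged as flatline.
#' @param clip_level Fraction of the stride maximum treated as the
#'   saturation plateau.
#' @param clip_frac Strides with more than this fraction of samples on
#'   the plateau are flagged as clipped.
#' @param rms_z Strides whose RMS leave-one-out z-score (against the
#'   remaining strides) exceeds this are flagged as amplitude outliers.
#' @return A list of rule thresholds.
#' @export
artifact_rules <- function(flatline_var = 1e-12, clip_level = 0.99,
                           clip_frac = 0.10, rms_z = 4) {
  list(flatline_var = flatline_var, clip_level = clip_level,
       clip_frac = clip_frac, rms_z = rms_z)
}

#' Screen strides for artifacts
#'
#' Removes strides failing any rule (flatline, clipping, amplitude
#' outlier) and any stride named in a user-supplied manual exclusion
#' list, reporting each exclusion with its reason.
#'
#' @param mat Per-stride matrix from [segment_strides()].
#' @param rules Thresholds from [artifact_rules()].
#' @param manual_exclude Integer stride indices to exclude regardless of
#'   the rules.
#' @return List with `mat` (retained strides, original indices as
#'   rownames) and `excluded` (data frame of `stride`, `reason`).
#' @export
screen_artifacts <- function(mat, rules = artifact_rules(),
                             manual_exclude = integer()) {
  if (!is.matrix(mat) || nrow(mat) < 1L) stopf("per-stride matrix is empty")
  n <- nrow(mat)
  rms <- sqrt(rowMeans(mat^2))
  reasons <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i %in% manual_exclude) { reasons[i] <- "manual"; next }
    if (stats::var(mat[i, ]) < rules$flatline_var) { reasons[i] <- "flatline"; next }
    mx <- max(abs(mat[i, ]))
    if (mx > 0 && mean(abs(mat[i, ]) >= rules$clip_level * mx) > rules$clip_frac) {
      reasons[i] <- "clipping"; next
    }
    others <- rms[-i]
    if (length(others) >= 2L) {
      s <- stats::sd(others)
      dev <- abs(rms[i] - mean(others))
      if ((s == 0 && dev > 1e-9 * max(rms[i], 1)) ||
          (s > 0 && dev / s > rules$rms_z))
        reasons[i] <- "amplitude_outlier"
    }
  }
  keep <- is.na(reasons)
  if (!any(keep)) stopf("no usable strides: all %d excluded", n)
  out <- mat[keep, , drop = FALSE]
  rownames(out) <- which(keep)
  list(mat = out,
       excluded = data.frame(stride = which(!keep),
                             reason = reasons[!keep]))
}

#' Peak-normalize a muscle's stride matrix
#'
#' Divides all retained strides of a muscle by that muscle's maximum over
#' the assessment, so the maximum normalized value is exactly 1.
#'
#' @param mat Per-stride matrix (retained strides of one muscle).
#' @return Normalized matrix with values in `[0, 1]`.
#' @export
peak_normalize <- function(mat) {
  m <- max(mat)
  if (!is.finite(m) || m <= 0) stopf("silent channel: peak amplitude is not positive")
  mat / m
}

#' Stimulated / non-stimulated activity ratio
#'
#' Mean of the stride-averaged normalized envelope inside the stimulation
#' window(s) of the gait cycle, divided by the mean outside. A small
#' epsilon guards the denominator; the guard sets `denominator_guarded`.
#'
#' @param envelope Per-stride matrix (strides x normalized grid) or a
#'   single stride-averaged profile vector.
#' @param stim_window Matrix with columns `start`, `end` of cycle
#'   fractions in `[0, 1]` (as from [cycle_window()]), or a single
#'   `c(start, end)`.
#' @param eps Denominator guard in normalized units.
#' @param muscle,side,assessment Optional labels carried into the result.
#' @return A one-row data frame: `muscle`, `side`, `assessment`,
#'   `mean_stim`, `mean_nonstim`, `ratio`, `denominator_guarded`.
#' @export
stim_ratio <- function(envelope, stim_window, eps = 1e-6,
                       muscle = NA_character_, side = NA_character_,
                       assessment = NA_character_) {
  prof <- if (is.matrix(envelope)) colMeans(envelope) else as.numeric(envelope)
  if (!is.matrix(stim_window)) stim_window <- matrix(stim_window, ncol = 2)
  if (any(stim_window < 0) || any(stim_window > 1) ||
      any(stim_window[, 2] <= stim_window[, 1]))
    stopf("stimulation windows must be non-empty sub-intervals of [0, 1]")
  frac <- seq(0, 1, length.out = length(prof))
  inside <- rep(FALSE, length(prof))
  for (r in seq_len(nrow(stim_window)))
    inside <- inside | (frac >= stim_window[r, 1] & frac <= stim_window[r, 2])
  if (!any(inside) || all(inside))
    stopf("both stimulated and non-stimulated cycle fractions must be non-empty")
  mean_stim <- mean(prof[inside])
  mean_nonstim <- mean(prof[!inside])
  guarded <- mean_nonstim < eps
  data.frame(muscle = muscle, side = side, assessment = assessment,
             mean_stim = mean_stim, mean_nonstim = mean_nonstim,
             ratio = mean_stim / max(mean_nonstim, eps),
             denominator_guarded = guarded)
}

#' Change in activity ratios across assessments
#'
#' Signed differences of the stimulated/non-stimulated ratio at
#' post-intervention and follow-up relative to baseline, per muscle and
#' side. Missing assessments produce `NA` gaps, not errors.
#'
#' @param ratios Data frame with columns `muscle`, `side`, `assessment`
#'   (one of `baseline`, `post`, `followup`) and `ratio`, e.g. rows from
#'   [stim_ratio()].
#' @return Data frame with `muscle`, `side`, `change_post`,
#'   `change_followup`.
#' @export
ratio_change <- function(ratios) {
  need <- c("muscle", "side", "assessment", "ratio")
  if (!all(need %in% names(ratios)))
    stopf("ratios must have columns %s", paste(need, collapse = ", "))
  keys <- unique(ratios[c("muscle", "side")])
  if (nrow(merge(keys, ratios)) < 2L)
    stopf("need >= 2 assessments sharing a muscle/side")
  get1 <- function(m, s, a) {
    r <- ratios$ratio[ratios$muscle == m & ratios$side == s &
                        ratios$assessment == a]
    if (length(r) == 0L) NA_real_ else r[1]
  }
  out <- keys
  out$change_post <- NA_real_
  out$change_followup <- NA_real_
  for (i in seq_len(nrow(keys))) {
    base <- get1(keys$muscle[i], keys$side[i], "baseline")
    out$change_post[i] <- get1(keys$muscle[i], keys$side[i], "post") - base
    out$change_followup[i] <- get1(keys$muscle[i], keys$side[i], "followup") - base
  }
  rownames(out) <- NULL
  out
}
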