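# Fixtures built in code: a reconstructed training log matching the
# study's printed aggregates, grid profiles for recovery studies, and a
# contact-matching helper.

# 5 participants x 20 planned sessions; per-participant missed counts
# {5, 2, 1, 1, 0}; 15 attended sessions carry technical issues
# (2 zipper, 7 imu, 6 connection), all resolved.
make_study_log <- function() {
  missed <- c(p1 = 5, p2 = 2, p3 = 1, p4 = 1, p5 = 0)
  rows <- list()
  issues <- c(rep("zipper", 2), rep("imu", 7), rep("connection", 6))
  issue_i <- 1L
  for (p in names(missed)) {
    for (s in 1:20) {
      att <- s > missed[[p]]          # first sessions of each participant missed
      issue <- "none"
      if (att && issue_i <= length(issues) && s %% 2 == 0) {
        issue <- issues[issue_i]
        issue_i <- issue_i + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p, session = s, attended = att,
        reason_missed = if (att) "" else "illness",
        duration_min = if (att) 30 else NA_real_,
        distance_m = if (att) 400 + 5 * s else NA_real_,
        technical_issue = issue,
        issue_resolved = if (issue == "none") "none" else "yes")
    }
  }
  session_log(do.call(rbind, rows))
}

# Self-consistent profile drawn from the recovery grid: speed 0.2-1.2 m/s,
# cadence 40-130 steps/min, step length derived from both.
grid_profile <- function(seed, noise_cm = 0.5) {
  v <- stats::runif(1, 0.2, 1.2)
  cad <- stats::runif(1, 40, 130)
  gait_profile(walking_speed = v, cadence = cad,
               step_length_mean = 100 * v * 60 / cad,
               noise_sd_trajectory = noise_cm, seed = seed)
}

# Absolute time offsets (s) from each interior ground-truth contact to the
# nearest detected contact. Truth contacts within `margin_strides` strides
# of the recording boundaries are excluded, mirroring the detector's edge
# policy.
contact_errors <- function(truth, detected, trial, stride_s,
                           margin_strides = 0.75) {
  tl <- range(trial$time_s)
  errs <- c()
  for (side in c("left", "right")) {
    tc <- truth[[side]]$contact
    tc <- tc[tc >= tl[1] + margin_strides * stride_s &
               tc <= tl[2] - margin_strides * stride_s]
    det <- detected[[side]]$contact
    errs <- c(errs, vapply(tc, function(x) min(abs(det - x)), 0))
  }
  errs
}

# The 50-trial recovery study shared by the event- and parameter-recovery
# acceptance checks; computed once and cached.
.acceptance_cache <- new.env(parent = emptyenv())
grid_results <- function() {
  if (!exists("res", envir = .acceptance_cache)) {
    set.seed(42)
    errs <- c()
    summaries <- vector("list", 50)
    for (i in 1:50) {
      p <- grid_profile(seed = 1000 + i, noise_cm = 0.5)
      g <- generate_trajectories(p)
      ev <- detect_gait_events(g$trial)
      errs <- c(errs, contact_errors(g$events, ev, g$trial, 120 / p$cadence))
      summaries[[i]] <- list(profile = p,
                             summary = spatiotemporal_summary(g$trial, ev))
    }
    assign("res", list(errs = errs, summaries = summaries),
           envir = .acceptance_cache)
  }
  get("res", envir = .acceptance_cache)
}

# Manual event set with one right-side single-support interval [1, 2] s,
# for step-location unit tests.
one_interval_events <- function() {
  gait_events(left = list(contact = c(0.9, 2.0), off = c(1.0)),
              right = list(contact = c(0.5), off = c(2.2)),
              source = "truth")
}
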