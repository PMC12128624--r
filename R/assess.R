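# Assessment workflow: one report per walkway pass (events,
# spatiotemporal summary, EMG envelopes and stimulation ratios), and a
# longitudinal comparison of baseline / post-intervention / follow-up
# reports.

ASSESSMENT_LABELS <- c("baseline", "post", "followup")
REPORT_SCHEMA_VERSION <- 1L

#' Assessment configuration
#'
#' @param trajectories Path to a trajectory CSV.
#' @param emg Optional path to an EMG CSV; `NULL` skips the EMG stage.
#' @param events Optional path to an events CSV; if `NULL`, events are
#'   detected from the trajectories.
#' @param schedule Optional path to a stimulation-schedule JSON; needed
#'   for the stimulated/non-stimulated ratios.
#' @param label Assessment label: baseline, post or followup.
#' @param walkway_length Walkway length in m.
#' @param window Measurement window in m.
#' @param filter_spec An [emg_filter_spec()].
#' @param detector An [event_config()].
#' @return A validated config list.
#' @export
assessment_config <- function(trajectories, emg = NULL, events = NULL,
                              schedule = NULL,
                              label = c("baseline", "post", "followup"),
                              walkway_length = 10, window = c(2, 8),
                              filter_spec = emg_filter_spec(),
                              detector = event_config()) {
  label <- match.arg(label)
  for (p in c(trajectories, emg, events, schedule))
    if (!file.exists(p)) stopf("file not found: %s", p)
  list(trajectories = trajectories, emg = emg, events = events,
       schedule = schedule, label = label, walkway_length = walkway_length,
       window = window, filter_spec = filter_spec, detector = detector)
}

# Stimulated muscle groups analysed for the activity ratio, and the EMG
# channel standing for each.
RATIO_MUSCLES <- c(VL = "quadriceps", ST = "hamstrings",
                   GAM = "gastrocnemius", TA = "tibialis_anterior")

#' Run one assessment
#'
#' Reads the configured files, detects (or loads) gait events, computes
#' the spatiotemporal summary and, when EMG is configured, the processed
#' stride-normalized envelopes and the stimulated/non-stimulated activity
#' ratio of VL, ST, GAM and TA against the schedule's cycle windows.
#' Deterministic given its inputs.
#'
#' @param config An [assessment_config()].
#' @return An `assessment_report` list.
#' @export
run_assessment <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  trial <- stage("trajectories",
                 read_trajectories(config$trajectories, config$walkway_length))
  events <- if (is.null(config$events)) {
    stage("events", detect_gait_events(trial, config$detector))
  } else {
    stage("events", read_events(config$events))
  }
  summary <- stage("spatiotemporal",
                   spatiotemporal_summary(trial, events, config$window))

  report <- list(schema_version = REPORT_SCHEMA_VERSION,
                 label = config$label,
                 events = list(left = events$left, right = events$right,
                               source = events$source),
                 spatiotemporal = list(
                   walking_speed_ms = summary$walking_speed_ms,
                   step_length_cm = summary$step_length_cm$mean,
                   step_width_cm = summary$step_width_cm$mean,
                   cadence_spm = summary$cadence_spm,
                   n_steps = summary$n_steps))

  if (!is.null(config$emg)) {
    rec <- stage("emg", read_emg(config$emg))
    env <- stage("emg", emg_filter_chain(rec, config$filter_spec))
    schedule <- if (!is.null(config$schedule)) read_schedule(config$schedule)
    ratios <- list()
    envelopes <- list()
    for (lab in colnames(env)) {
      muscle <- sub("_[LR]$", "", lab)
      side <- if (grepl("_L$", lab)) "left" else "right"
      strided <- stage("emg", segment_strides(env[, lab], events, side,
                                              fs = rec$sampling_rate))
      screened <- stage("emg", screen_artifacts(strided))
      norm <- stage("emg", peak_normalize(screened$mat))
      envelopes[[lab]] <- list(profile = colMeans(norm),
                               n_strides = nrow(norm),
                               excluded = screened$excluded$stride)
      if (!is.null(schedule) && muscle %in% names(RATIO_MUSCLES)) {
        win <- cycle_window(schedule, RATIO_MUSCLES[[muscle]], side)
        ratios[[lab]] <- stim_ratio(norm, win, muscle = muscle, side = side,
                                    assessment = config$label)
      }
    }
    report$emg <- envelopes
    if (length(ratios)) report$stim_ratios <- do.call(rbind, ratios)
  }
  structure(report, class = "assessment_report")
}

#' Write / read an assessment report (JSON)
#'
#' @param report An `assessment_report`.
#' @param path File path.
#' @return `write_report` returns the path invisibly; `read_report`
#'   returns the report.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(r$stim_ratios)) r$stim_ratios <- as.data.frame(r$stim_ratios)
  structure(r, class = "assessment_report")
}

#' Compare assessments against baseline
#'
#' Signed per-parameter differences of each report against the baseline
#' report, plus activity-ratio changes when ratios are present. Missing
#' assessments produce gaps, not errors.
#'
#' @param ... Two or more `assessment_report` objects with distinct
#'   labels, one of them `baseline`.
#' @return List with `spatiotemporal` (data frame of differences per
#'   assessment) and, if available, `ratio_changes`.
#' @export
compare_assessments <- function(...) {
  reports <- list(...)
  if (length(reports) == 1L && !inherits(reports[[1]], "assessment_report"))
    reports <- reports[[1]]
  labels <- vapply(reports, function(r) r$label, "")
  if (length(reports) < 2L || anyDuplicated(labels))
    stopf("need >= 2 reports with distinct labels, got: %s",
          paste(labels, collapse = ", "))
  if (!"baseline" %in% labels) stopf("a 'baseline' report is required")
  base <- reports[[which(labels == "baseline")]]
  params <- c("walking_speed_ms", "step_length_cm", "step_width_cm",
              "cadence_spm")
  diffs <- list()
  for (r in reports[labels != "baseline"]) {
    d <- vapply(params, function(p)
      r$spatiotemporal[[p]] - base$spatiotemporal[[p]], 0)
    diffs[[r$label]] <- data.frame(assessment = r$label, t(d))
  }
  out <- list(spatiotemporal = do.call(rbind, diffs))
  rownames(out$spatiotemporal) <- NULL
  all_ratios <- do.call(rbind, lapply(reports, function(r) r$stim_ratios))
  if (!is.null(all_ratios) && "baseline" %in% all_ratios$assessment)
    out$ratio_changes <- ratio_change(all_ratios)
  out
}
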