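# Plain-text round-tripping of the toolkit's formats:
#   trajectories.csv  time_s, point, x_m, y_m, z_m
#   emg.csv           time_s, then one column per channel <MUSCLE>_<L|R>
#   events.csv        side, event (foot_contact|foot_off), time_s
#   profile.json      all gait_profile fields
#   schedule.json     channel specs + cycle_duration_ms
#   stim_truth.csv    channel, start_s, end_s
#   session log CSV   participant, session, attended, ...

write_num_csv <- function(df, path) {
  utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
}

#' Write a synthetic trial as a fixture directory
#'
#' Emits the CSV/JSON files above; all numeric fields round-trip through
#' the matching readers to within 1e-9.
#'
#' @param trial A [synthetic_trial()].
#' @param directory Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(trial, directory) {
  stopifnot(inherits(trial, "synthetic_trial"))
  if (is.null(trial$trajectories) || length(trial$trajectories$time_s) == 0L)
    stopf("empty trial: nothing to write")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    trajectories = file.path(directory, "trajectories.csv"),
    emg = file.path(directory, "emg.csv"),
    events = file.path(directory, "events_truth.csv"),
    profile = file.path(directory, "profile.json"),
    schedule = file.path(directory, "schedule.json"),
    stim = file.path(directory, "stim_truth.csv"))
  write_trajectories(trial$trajectories, paths["trajectories"])
  write_emg(trial$emg, paths["emg"])
  write_events(trial$events_truth, paths["events"])
  write_profile(trial$profile, paths["profile"])
  write_schedule(trial$schedule, paths["schedule"])
  iv <- trial$stim_truth$intervals
  stim_df <- do.call(rbind, lapply(names(iv), function(nm) {
    if (nrow(iv[[nm]]) == 0L) return(NULL)
    data.frame(channel = nm, start_s = iv[[nm]][, 1], end_s = iv[[nm]][, 2])
  }))
  if (is.null(stim_df))
    stim_df <- data.frame(channel = character(), start_s = numeric(),
                          end_s = numeric())
  write_num_csv(stim_df, paths["stim"])
  invisible(paths)
}

#' @rdname write_fixture
#' @param x Object to write.
#' @param path File path.
#' @export
write_trajectories <- function(x, path) {
  stopifnot(inherits(x, "trajectory_trial"))
  long <- do.call(rbind, lapply(names(x$points), function(nm)
    data.frame(time_s = x$time_s, point = nm,
               x_m = x$points[[nm]]$x, y_m = x$points[[nm]]$y,
               z_m = x$points[[nm]]$z)))
  write_num_csv(long, path)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' @param path File written by [write_trajectories()].
#' @param walkway_length Walkway length in m (not stored in the CSV).
#' @return A [trajectory_trial()].
#' @export
read_trajectories <- function(path, walkway_length = 10) {
  df <- utils::read.csv(path)
  need <- c("time_s", "point", "x_m", "y_m", "z_m")
  if (!all(need %in% names(df)))
    stopf("%s: expected columns %s", path, paste(need, collapse = ", "))
  pts <- lapply(split(df, df$point), function(d) {
    d <- d[order(d$time_s), ]
    data.frame(x = d$x_m, y = d$y_m, z = d$z_m)
  })
  time_s <- sort(unique(df$time_s))
  fs <- 1 / stats::median(diff(time_s))
  trajectory_trial(time_s, pts, sampling_rate = fs,
                   walkway_length = walkway_length)
}

#' @rdname write_fixture
#' @export
write_emg <- function(x, path) {
  stopifnot(inherits(x, "emg_recording"))
  df <- data.frame(time_s = emg_time(x), x$signals, check.names = FALSE)
  write_num_csv(df, path)
  invisible(path)
}

#' Read an EMG CSV
#'
#' @param path File written by [write_emg()].
#' @return An [emg_recording()].
#' @export
read_emg <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time_s") stopf("%s: first column must be time_s", path)
  fs <- 1 / stats::median(diff(df$time_s))
  emg_recording(as.matrix(df[-1]), sampling_rate = fs)
}

#' @rdname write_fixture
#' @export
write_events <- function(x, path) {
  stopifnot(inherits(x, "gait_events"))
  rows <- list()
  for (side in SIDES) {
    rows[[length(rows) + 1L]] <- data.frame(side = side, event = "foot_contact",
                                            time_s = x[[side]]$contact)
    rows[[length(rows) + 1L]] <- data.frame(side = side, event = "foot_off",
                                            time_s = x[[side]]$off)
  }
  write_num_csv(do.call(rbind, rows), path)
  invisible(path)
}

#' Read a gait-events CSV
#'
#' @param path File written by [write_events()].
#' @param source Label for the event source.
#' @return A [gait_events()].
#' @export
read_events <- function(path, source = "truth") {
  df <- utils::read.csv(path)
  pick <- function(side, event) sort(df$time_s[df$side == side & df$event == event])
  gait_events(left = list(contact = pick("left", "foot_contact"),
                          off = pick("left", "foot_off")),
              right = list(contact = pick("right", "foot_contact"),
                           off = pick("right", "foot_off")),
              source = source)
}

#' @rdname write_fixture
#' @export
write_profile <- function(x, path) {
  stopifnot(inherits(x, "gait_profile"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a gait-profile JSON
#'
#' @param path File written by [write_profile()].
#' @return A [gait_profile()].
#' @export
read_profile <- function(path) {
  do.call(gait_profile, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname write_fixture
#' @export
write_schedule <- function(x, path) {
  stopifnot(inherits(x, "stim_schedule"))
  jsonlite::write_json(list(cycle_duration_ms = x$cycle_duration_ms,
                            channels = lapply(x$channels, unclass)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a stimulation-schedule JSON
#'
#' @param path File written by [write_schedule()].
#' @return A [stim_schedule()].
#' @export
read_schedule <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  stim_schedule(lapply(j$channels, function(ch) do.call(stim_channel_spec, ch)),
                cycle_duration_ms = j$cycle_duration_ms)
}

#' Read a session-log CSV
#'
#' @param path CSV with the [session_log()] columns.
#' @return A [session_log()].
#' @export
read_session_log <- function(path) {
  session_log(utils::read.csv(path))
}
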