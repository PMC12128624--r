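# Feasibility and safety analytics over training-session logs and
# questionnaire responses.

ISSUE_CATEGORIES <- c("zipper", "imu", "connection")

#' Build/validate a session log
#'
#' @param df Data frame with columns `participant`, `session` (1..planned,
#'   unique per participant), `attended` (logical or yes/no),
#'   `reason_missed`, `duration_min`, `distance_m`, `technical_issue`
#'   (none/zipper/imu/connection), `issue_resolved` (yes/no/partial).
#' @return The validated data frame, class `session_log`.
#' @export
session_log <- function(df) {
  df <- as.data.frame(df)
  need <- c("participant", "session", "attended")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("session log lacks column(s): %s", paste(miss, collapse = ", "))
  if (is.character(df$attended)) df$attended <- tolower(df$attended) %in% c("yes", "true", "1")
  df$attended <- as.logical(df$attended)
  for (col in c("reason_missed", "duration_min", "distance_m",
                "technical_issue", "issue_resolved"))
    if (is.null(df[[col]]))
      df[[col]] <- if (col %in% c("duration_min", "distance_m")) NA_real_ else "none"
  bad <- !df$technical_issue %in% c("none", ISSUE_CATEGORIES)
  if (any(bad))
    stopf("unknown technical_issue value(s): %s",
          paste(unique(df$technical_issue[bad]), collapse = ", "))
  dup <- duplicated(df[c("participant", "session")])
  if (any(dup)) stopf("duplicate (participant, session) row(s)")
  class(df) <- c("session_log", "data.frame")
  df
}

#' Session adherence and missed-session statistics
#'
#' Adherence is attended sessions over planned sessions, in percent.
#' Missed-session mean and SD are computed over participants (sample SD,
#' n-1 denominator; `NA` for a single participant). Sessions where an
#' unresolved technical issue prevented stimulation can be reclassified
#' as missed.
#'
#' @param log A [session_log()].
#' @param planned_per_participant Planned sessions per participant; every
#'   participant must have exactly this many rows.
#' @param reclassify_unresolved If `TRUE` (default), attended sessions
#'   with `technical_issue != "none"` and `issue_resolved == "no"` count
#'   as missed.
#' @return List with `adherence_pct`, `missed_mean`, `missed_sd`,
#'   `missed_by_participant`, `n_participants`, `planned_total`.
#' @export
adherence_summary <- function(log, planned_per_participant,
                              reclassify_unresolved = TRUE) {
  log <- session_log(log)
  counts <- table(log$participant)
  gaps <- names(counts)[counts != planned_per_participant]
  if (length(gaps))
    stopf("participant(s) without %d session rows: %s",
          planned_per_participant, paste(gaps, collapse = ", "))
  attended <- log$attended
  if (reclassify_unresolved)
    attended <- attended & !(log$technical_issue != "none" &
                               log$issue_resolved == "no")
  missed <- tapply(!attended, log$participant, sum)
  planned_total <- length(counts) * planned_per_participant
  list(adherence_pct = 100 * sum(attended) / planned_total,
       missed_mean = mean(missed),
       missed_sd = if (length(missed) > 1L) stats::sd(missed) else NA_real_,
       missed_by_participant = missed,
       n_participants = length(counts),
       planned_total = planned_total)
}

#' Technical-issue summary
#'
#' Counts sessions with a non-none technical issue by category, their
#' total, and the resolution breakdown.
#'
#' @param log A [session_log()].
#' @return List with `counts` (named by category), `total`, `resolution`
#'   (table over yes/no/partial among issue sessions).
#' @export
issue_summary <- function(log) {
  log <- session_log(log)
  has_issue <- log$technical_issue != "none"
  counts <- vapply(ISSUE_CATEGORIES,
                   function(cat) sum(log$technical_issue == cat), 0L)
  list(counts = counts,
       total = sum(counts),
       resolution = table(factor(log$issue_resolved[has_issue],
                                 levels = c("yes", "partial", "no"))))
}

#' Default questionnaire scales
#'
#' Item scales of the post-intervention feasibility questionnaire:
#' satisfaction 0-10, desired session frequency 1-4, preferred duration,
#' comfort, donning, doffing and helpfulness 1-5.
#'
#' @return Data frame with columns `item`, `min`, `max`.
#' @export
question_scales <- function() {
  data.frame(item = c("satisfaction", "frequency", "duration", "comfort",
                      "donning", "doffing", "helpfulness"),
             min = c(0, 1, 1, 1, 1, 1, 1),
             max = c(10, 4, 5, 5, 5, 5, 5))
}

#' Questionnaire medians per item
#'
#' @param responses Data frame with columns `item`, `participant`,
#'   `score`.
#' @param scales Data frame of per-item scale bounds; defaults to
#'   [question_scales()].
#' @return Named numeric vector of medians per item.
#' @export
questionnaire_medians <- function(responses, scales = question_scales()) {
  responses <- as.data.frame(responses)
  need <- c("item", "participant", "score")
  if (!all(need %in% names(responses)))
    stopf("responses must have columns %s", paste(need, collapse = ", "))
  m <- match(responses$item, scales$item)
  if (anyNA(m))
    stopf("item(s) without a declared scale: %s",
          paste(unique(responses$item[is.na(m)]), collapse = ", "))
  bad <- responses$score < scales$min[m] | responses$score > scales$max[m]
  if (any(bad)) {
    i <- which(bad)[1]
    stopf("row %d: score %g outside the %g-%g scale of item '%s'",
          i, responses$score[i], scales$min[m[i]], scales$max[m[i]],
          responses$item[i])
  }
  vapply(split(responses$score, responses$item), stats::median, 0)
}

#' Training-distance series relative to the first session
#'
#' Per participant, the percent difference in walked distance of each
#' session compared with the first session. Sessions that were missed or
#' lasted less than `min_duration_min` get linearly interpolated values
#' (constant-extended at the tail) and are flagged.
#'
#' @param log A [session_log()] with `distance_m` and `duration_min`.
#' @param min_duration_min Minimum session duration counted as valid.
#' @return Data frame with `participant`, `session`, `pct_diff`,
#'   `interpolated`.
#' @export
training_distance_series <- function(log, min_duration_min = 30) {
  log <- session_log(log)
  out <- list()
  for (p in unique(log$participant)) {
    d <- log[log$participant == p, ]
    d <- d[order(d$session), ]
    valid <- d$attended & !is.na(d$distance_m) &
      !is.na(d$duration_min) & d$duration_min >= min_duration_min
    if (!valid[1])
      stopf("participant %s: first session missing or invalid; no reference distance", p)
    ref <- d$distance_m[1]
    pct <- ifelse(valid, 100 * (d$distance_m - ref) / ref, NA_real_)
    if (anyNA(pct))
      pct <- stats::approx(d$session[valid], pct[valid], xout = d$session,
                           rule = 2)$y
    out[[length(out) + 1L]] <- data.frame(participant = p,
                                          session = d$session,
                                          pct_diff = pct,
                                          interpolated = !valid)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
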