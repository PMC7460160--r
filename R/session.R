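#' Construct a game event
#'
#' Events are the state alterations the adaptation component observes to
#' populate the user model: `activityStarted` flags a scenario start,
#' `activityFinished` marks its end (carrying a `completed` flag so the
#' score can be trusted), `scoreObtained` saves the final score,
#' `registerPostAnalytics` and `executionMovement` are recorded for schema
#' completeness but drive no behaviour (their customizations were pruned),
#' and `signalActivation` marks the start of physiological data collection.
#'
#' @param kind Event kind, one of the six listed above.
#' @param t Event time, seconds since session start.
#' @param scenario Scenario id (`1`, `2`, `3` or `"test"`).
#' @param payload Named list of details (e.g. `completed` for
#'   `activityFinished`, `score` for `scoreObtained`).
#' @return A list of class `game_event`.
#' @export
game_event <- function(kind, t, scenario = NA, payload = list()) {
  kind <- match.arg(kind, GAME_EVENT_KINDS)
  if (identical(kind, "activityFinished") && is.null(payload$completed)) {
    stop("activityFinished must carry a 'completed' flag")
  }
  structure(list(kind = kind, t = as.numeric(t),
                 scenario = as.character(scenario), payload = payload),
            class = "game_event")
}

GAME_EVENT_KINDS <- c("activityStarted", "activityFinished", "scoreObtained",
                      "registerPostAnalytics", "executionMovement",
                      "signalActivation")

#' An empty user-model record
#'
#' The user model consolidates the properties the adaptation component
#' collects: the history of played scenarios with start/end and completion,
#' the final score of each completed play (latest per play; all retrievable
#' from the history), per-scenario play counts, configuration-parameter
#' history, and a reference to the session's physiological signal stream.
#'
#' @param physiological_signals Optional reference (e.g. a file path or an
#'   [hr_stream()]) to the session's HR/kcal stream.
#' @return A list of class `user_model_record` with fields
#'   `activitiesHistory`, `scoreRecord`, `scenarioCounter`,
#'   `confParamHistory`, `physiologicalSignals` and internal bookkeeping of
#'   the open activity.
#' @export
user_model_record <- function(physiological_signals = NULL) {
  structure(list(activitiesHistory = list(), scoreRecord = list(),
                 scenarioCounter = integer(0), confParamHistory = list(),
                 physiologicalSignals = physiological_signals,
                 .open = NULL),
            class = "user_model_record")
}

#' Fold one event into the user-model record
#'
#' Applies the event/user-property linkage: `activityStarted` opens a new
#' history entry and increments the scenario counter; `activityFinished`
#' closes it with its completion flag; `scoreObtained` appends to the score
#' record only when the activity it follows completed normally (a score
#' after an incomplete finish is discarded, securing a correct score
#' record); `scoreObtained` with no activity ever started is a sequencing
#' error. Analytics events are appended to the configuration history
#' verbatim.
#'
#' @param record A [user_model_record()].
#' @param event A [game_event()].
#' @return The updated `user_model_record`.
#' @export
emit_event <- function(record, event) {
  stopifnot(inherits(record, "user_model_record"),
            inherits(event, "game_event"))
  sc <- event$scenario
  switch(event$kind,
    activityStarted = {
      record$.open <- list(scenario = sc, start = event$t, end = NA_real_,
                           completed = NA)
      n <- record$scenarioCounter[sc]
      record$scenarioCounter[sc] <- if (is.na(n)) 1L else n + 1L
    },
    activityFinished = {
      if (is.null(record$.open)) stop("activityFinished with no open activity")
      record$.open$end <- event$t
      record$.open$completed <- isTRUE(event$payload$completed)
      record$activitiesHistory[[length(record$activitiesHistory) + 1L]] <-
        record$.open
    },
    scoreObtained = {
      if (is.null(record$.open)) {
        stop("sequencing error: scoreObtained with no matching activity")
      }
      if (isTRUE(record$.open$completed) || is.na(record$.open$completed)) {
        record$scoreRecord[[length(record$scoreRecord) + 1L]] <-
          list(scenario = sc, score = event$payload$score)
      }
      if (!is.na(record$.open$completed)) record$.open <- NULL
    },
    registerPostAnalytics = ,
    executionMovement = ,
    signalActivation = {
      record$confParamHistory[[length(record$confParamHistory) + 1L]] <-
        list(key = event$kind, value = event$payload, t = event$t)
    })
  record
}

#' Assemble a session log
#'
#' A session log is the full 1 Hz record of one participant-arm play
#' session: per-tick raw and calibrated HR, the window statistics the
#' controllers consumed, the active scenario, a JSON snapshot of the
#' controller state (including the tick's inputs, which makes the log
#' replayable), the running score and the per-scenario cumulative calorie
#' estimate, plus the list of game events.
#'
#' @param participant Participant identifier.
#' @param arm `"UAS"` (adaptive) or `"CIS"` (frozen difficulty).
#' @param rows `data.frame` with columns
#'   `t, hr_raw, hr_cal, avg_hr, w, scenario, state_json, points, kcal`;
#'   timestamps strictly increasing, kcal non-decreasing within a scenario.
#' @param events List of [game_event()]s.
#' @return A list of class `session_log`.
#' @export
session_log <- function(participant, arm = c("UAS", "CIS"),
                        rows, events = list()) {
  arm <- match.arg(arm)
  need <- c("t", "hr_raw", "hr_cal", "avg_hr", "w", "scenario",
            "state_json", "points", "kcal")
  miss <- setdiff(need, names(rows))
  if (length(miss) > 0L) {
    stop("session rows missing column(s): ", paste(miss, collapse = ", "))
  }
  rows <- rows[, need]
  log <- structure(list(participant = as.character(participant), arm = arm,
                        rows = rows, events = events),
                   class = "session_log")
  validate_session_log(log)
  log
}

#' Validate session-log invariants
#'
#' Checks that row timestamps are strictly increasing and that cumulative
#' kcal never decreases within a scenario segment (it resets when a new
#' scenario starts). Violations are reported with the offending row number.
#'
#' @param log A [session_log()].
#' @return The log, invisibly; stops with an informative error otherwise.
#' @export
validate_session_log <- function(log) {
  r <- log$rows
  if (nrow(r) > 1L) {
    bad <- which(diff(r$t) <= 0)
    if (length(bad) > 0L) {
      stop(sprintf("invariant violation at row %d: timestamps not strictly increasing",
                   bad[1] + 1L))
    }
    same <- r$scenario[-1L] == r$scenario[-nrow(r)]
    drop <- which(same & diff(r$kcal) < 0)
    if (length(drop) > 0L) {
      stop(sprintf("invariant violation at row %d: cumulative kcal decreased within a scenario",
                   drop[1] + 1L))
    }
  }
  invisible(log)
}

#' Write a session log to disk
#'
#' Writes the 1 Hz rows as `<path>.csv` (comma-separated, UTF-8, dot
#' decimal) and the events as a `<path>.events.jsonl` sidecar, one JSON
#' object per line. Numeric columns are serialised at full double
#' precision so that [read_session_log()] round-trips losslessly.
#'
#' @param log A [session_log()].
#' @param path Output path stem (without extension).
#' @return The paths written, invisibly.
#' @export
write_session_log <- function(log, path) {
  validate_session_log(log)
  csv <- paste0(path, ".csv")
  jl <- paste0(path, ".events.jsonl")
  r <- log$rows
  fmt <- function(x) {
    ifelse(x == floor(x) & abs(x) < 1e15, sprintf("%.0f", x),
           sprintf("%.17g", x))
  }
  header <- "t,hr_raw,hr_cal,avg_hr,w,scenario,state_json,points,kcal"
  lines <- sprintf("%s,%s,%s,%s,%s,%s,\"%s\",%d,%s",
                   fmt(r$t), fmt(r$hr_raw), fmt(r$hr_cal), fmt(r$avg_hr),
                   fmt(r$w), r$scenario, gsub("\"", "\"\"", r$state_json),
                   as.integer(r$points), fmt(r$kcal))
  meta <- sprintf("# participant=%s arm=%s", log$participant, log$arm)
  writeLines(c(meta, header, lines), csv, useBytes = TRUE)
  ev <- vapply(log$events, function(e) {
    jsonlite::toJSON(list(kind = e$kind, t = e$t, scenario = e$scenario,
                          payload = e$payload),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(ev, jl, useBytes = TRUE)
  invisible(c(csv = csv, events = jl))
}

#' Read a session log from disk
#'
#' Reads the CSV/JSONL pair written by [write_session_log()], validates all
#' session-log invariants (reporting the offending row on violation) and
#' reconstructs an identical [session_log()].
#'
#' @param path Path stem or the `.csv` path itself.
#' @return A `session_log`.
#' @export
read_session_log <- function(path) {
  csv <- if (grepl("\\.csv$", path)) path else paste0(path, ".csv")
  stem <- sub("\\.csv$", "", csv)
  jl <- paste0(stem, ".events.jsonl")
  lines <- readLines(csv, encoding = "UTF-8")
  meta <- lines[1]
  m <- regmatches(meta, regexec("^# participant=(.*) arm=(UAS|CIS)$", meta))[[1]]
  if (length(m) != 3L) stop("parse error: malformed metadata line")
  header <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  need <- c("t", "hr_raw", "hr_cal", "avg_hr", "w", "scenario",
            "state_json", "points", "kcal")
  miss <- setdiff(need, header)
  if (length(miss) > 0L) {
    stop("parse error: missing column ", paste(miss, collapse = ", "))
  }
  rows <- utils::read.csv(text = lines[-1], stringsAsFactors = FALSE,
                          colClasses = c(scenario = "character"))
  for (col in c("t", "hr_raw", "hr_cal", "avg_hr", "w", "kcal")) {
    rows[[col]] <- as.numeric(rows[[col]])
  }
  rows$points <- as.integer(rows$points)
  events <- if (file.exists(jl)) {
    lapply(readLines(jl, encoding = "UTF-8"), function(l) {
      o <- jsonlite::fromJSON(l, simplifyVector = TRUE)
      game_event(o$kind, o$t, o$scenario, as.list(o$payload))
    })
  } else list()
  session_log(m[2], m[3], rows, events)
}

#' Build the user model implied by a session log
#'
#' Folds the log's events through [emit_event()] in order.
#'
#' @param log A [session_log()].
#' @return A [user_model_record()].
#' @export
user_model_from_log <- function(log) {
  Reduce(emit_event, log$events, init = user_model_record())
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> participant %s, arm %s: %d rows, %d events\n",
              x$participant, x$arm, nrow(x$rows), length(x$events)))
  invisible(x)
}
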