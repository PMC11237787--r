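## Session-file IO (JSON Lines, one session per line, UTF-8/LF) and the
## cohort CSV.

.sessionToJSON <- function(s) {
  strokes <- s@strokes
  strokeList <- lapply(seq_len(nrow(strokes)), function(i) {
    list(component = strokes$component[i],
         event_span = c(strokes$start[i], strokes$end[i]))
  })
  jsonlite::toJSON(
    list(subject_id = s@subjectId,
         task_id = s@taskId,
         session_end_ms = s@sessionEndMs,
         events = s@events,
         strokes = strokeList,
         annotation = s@annotation),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", null = "null")
}

.sessionFromRecord <- function(rec, line) {
  fail <- function(...) stop("line ", line, ": ", ..., call. = FALSE)
  need <- c("subject_id", "task_id", "session_end_ms", "events", "strokes")
  miss <- setdiff(need, names(rec))
  if (length(miss)) fail("missing field(s) ", paste(miss, collapse = ", "))
  if (!rec$task_id %in% .TASK_TABLE$task_id)
    fail("unknown task_id '", rec$task_id, "'")
  ev <- rec$events
  if (!is.data.frame(ev)) ev <- as.data.frame(ev)
  if (!all(c("t", "x", "y", "phase", "source") %in% names(ev)))
    fail("events must have fields t, x, y, phase, source")
  sk <- rec$strokes
  if (is.data.frame(sk)) {
    comp <- as.character(sk$component)
    span <- sk$event_span
    spans <- if (is.matrix(span)) span else do.call(rbind, span)
  } else if (is.list(sk) && length(sk)) {
    comp <- vapply(sk, function(x) as.character(x$component), character(1))
    spans <- do.call(rbind, lapply(sk, function(x) as.integer(x$event_span)))
  } else {
    comp <- character(); spans <- matrix(integer(), 0, 2)
  }
  strokes <- data.frame(component = comp,
                        start = as.integer(spans[, 1]),
                        end = as.integer(spans[, 2]))
  ann <- rec$annotation
  if (is.null(ann)) ann <- list()
  s <- tryCatch(
    drawingSession(rec$subject_id, rec$task_id, ev, strokes, ann,
                   rec$session_end_ms, strict = FALSE),
    error = function(e) fail(conditionMessage(e)))
  v <- validateSession(s)
  if (length(v)) fail("invalid session: ", paste(v, collapse = "; "))
  s
}

#' Read sessions from a JSON-Lines file
#'
#' One session object per line:
#' `{subject_id, task_id, session_end_ms, events:[{t,x,y,phase,source}],`
#' `strokes:[{component, event_span:[i,j]}], annotation:{...}}` with 1-based
#' inclusive event spans. Records violating the data-model invariants are
#' rejected with the offending line number.
#'
#' @param path Path to the session file.
#' @return List of [DrawingSession-class] objects.
#' @export
readSessions <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e)
                      stop("line ", i, ": JSON parse error: ",
                           conditionMessage(e), call. = FALSE))
    .sessionFromRecord(rec, i)
  })
}

#' Write sessions to a JSON-Lines file
#'
#' @param sessions List of [DrawingSession-class] objects.
#' @param path Output path (UTF-8, LF line endings).
#' @return `path`, invisibly.
#' @export
writeSessions <- function(sessions, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (s in sessions) {
    writeLines(.sessionToJSON(s), con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Read / write the cohort table
#'
#' The cohort file is a headered CSV with one row per subject: `subject_id`,
#' `group` (`HC`/`MCI`), `age`, `gender` (`man`/`woman`), `hand_preference`
#' (`left`/`right`), `education_years`, `sleep_hours`, `exercise_habit`
#' (`yes`/`no`), `device_years`, `moca` (0-30), `mmse` (0-30), `cdr`.
#'
#' @param path CSV path.
#' @return `readCohort`: a `data.frame` of subjects.
#' @export
readCohort <- function(path) {
  sub <- read.csv(path, stringsAsFactors = FALSE)
  v <- .validateSubjects(sub)
  if (length(v)) stop("invalid cohort file: ", paste(v, collapse = "; "),
                      call. = FALSE)
  sub
}

#' @param subjects Subject `data.frame`.
#' @rdname readCohort
#' @export
writeCohort <- function(subjects, path) {
  write.csv(subjects, path, row.names = FALSE)
  invisible(path)
}

.validateSubjects <- function(sub) {
  v <- character()
  need <- c("subject_id", "group", "age", "gender", "hand_preference",
            "education_years", "sleep_hours", "exercise_habit",
            "device_years", "moca", "mmse", "cdr")
  miss <- setdiff(need, names(sub))
  if (length(miss))
    return(paste0("missing column(s) ", paste(miss, collapse = ", ")))
  if (any(!sub$group %in% c("HC", "MCI")))
    v <- c(v, "group: must be HC or MCI")
  if (any(sub$moca < 0 | sub$moca > 30))
    v <- c(v, "moca: outside instrument range 0-30")
  if (any(sub$mmse < 0 | sub$mmse > 30))
    v <- c(v, "mmse: outside instrument range 0-30")
  if (any(!sub$cdr %in% c(0, 0.5, 1, 2, 3)))
    v <- c(v, "cdr: must be one of 0, 0.5, 1, 2, 3")
  mci <- sub$group == "MCI"
  if (any(mci & (sub$moca >= 26 | sub$cdr != 0.5)))
    v <- c(v, "eligibility: MCI subjects require moca < 26 and cdr = 0.5")
  v
}
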