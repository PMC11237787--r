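## Event-stream segmentation and session validation.

#' Segment an event stream into strokes
#'
#' A stroke is a maximal `down` .. `up` run. Move events between an `up` and
#' the next `down` are in-air travel: they are legal but belong to no stroke.
#' Moves inside a stroke are optional (`down` immediately followed by `up` is
#' a valid dot stroke).
#'
#' @param events Event `data.frame` with columns `t` and `phase` (and
#'   usually `x`, `y`, `source`).
#' @return `data.frame` with columns `start`, `end` (1-based inclusive event
#'   indices) and `duration_ms`, one row per stroke in temporal order.
#' @export
#' @examples
#' ev <- data.frame(t = c(0, 50, 100, 300, 400), x = 0, y = 0,
#'                  phase = c("down", "move", "up", "down", "up"),
#'                  source = "stylus")
#' segmentStrokes(ev)
segmentStrokes <- function(events) {
  events <- as.data.frame(events)
  n <- nrow(events)
  if (!n) return(data.frame(start = integer(), end = integer(),
                            duration_ms = integer()))
  t <- as.integer(events$t)
  phase <- as.character(events$phase)
  if (any(!phase %in% .PHASES)) {
    i <- which(!phase %in% .PHASES)[1]
    stop("malformed stream: unknown phase '", phase[i], "' at event ", i,
         call. = FALSE)
  }
  if (any(diff(t) < 0)) {
    i <- which(diff(t) < 0)[1] + 1L
    stop("malformed stream: time decreases at event ", i, call. = FALSE)
  }
  starts <- integer(); ends <- integer()
  penDown <- FALSE
  seenStroke <- FALSE
  for (i in seq_len(n)) {
    p <- phase[i]
    if (p == "down") {
      if (penDown)
        stop("malformed stream: down at event ", i,
             " while pen already down", call. = FALSE)
      penDown <- TRUE
      starts <- c(starts, i)
    } else if (p == "up") {
      if (!penDown)
        stop("malformed stream: up at event ", i,
             " with no matching down", call. = FALSE)
      penDown <- FALSE
      seenStroke <- TRUE
      ends <- c(ends, i)
    } else { # move
      if (!penDown && !seenStroke)
        stop("malformed stream: move at event ", i,
             " before the first down", call. = FALSE)
    }
  }
  if (penDown)
    stop("malformed stream: down at event ", starts[length(starts)],
         " never matched by an up", call. = FALSE)
  data.frame(start = starts, end = ends,
             duration_ms = t[ends] - t[starts])
}

#' Validate a session against the data-model invariants
#'
#' Total function: returns a character vector of violations (empty when the
#' session is well formed). Checked rules: event fields and phase legality,
#' non-decreasing time, stroke spans matching the down..up segmentation,
#' component labels drawn from the task's permitted set, and
#' `sessionEndMs >= t` of the last event.
#'
#' @param session A [DrawingSession-class].
#' @return Character vector of violations, each naming field and rule.
#' @export
validateSession <- function(session) {
  v <- character()
  ev <- session@events
  task <- session@taskId
  if (!task %in% .TASK_TABLE$task_id) {
    v <- c(v, paste0("taskId: unknown task '", task, "'"))
    return(v)
  }
  if (nrow(ev)) {
    if (any(is.na(ev$t)) || any(ev$t < 0))
      v <- c(v, "events.t: times must be non-negative integers")
    if (any(diff(ev$t) < 0))
      v <- c(v, paste0("events.t: non-decreasing order violated at event ",
                       which(diff(ev$t) < 0)[1] + 1L))
    if (any(!ev$phase %in% .PHASES))
      v <- c(v, "events.phase: must be one of down, move, up")
    if (any(!ev$source %in% .SOURCES))
      v <- c(v, "events.source: must be one of stylus, drag")
  }
  seg <- tryCatch(segmentStrokes(ev), error = function(e) conditionMessage(e))
  if (is.character(seg)) {
    v <- c(v, paste0("events.phase: ", seg))
    return(v)
  }
  st <- session@strokes
  if (nrow(st) != nrow(seg)) {
    v <- c(v, sprintf("strokes: %d stroke rows but %d down..up runs",
                      nrow(st), nrow(seg)))
  } else if (nrow(st) &&
             (!identical(as.integer(st$start), as.integer(seg$start)) ||
              !identical(as.integer(st$end), as.integer(seg$end)))) {
    v <- c(v, "strokes: start/end spans do not match the segmentation")
  }
  allowed <- taskComponents(task)
  bad <- setdiff(st$component[!is.na(st$component)], allowed)
  if (length(bad))
    v <- c(v, paste0("strokes.component: label(s) ",
                     paste(unique(bad), collapse = ", "),
                     " not permitted for task ", task))
  if (nrow(ev) && session@sessionEndMs < max(ev$t))
    v <- c(v, "sessionEndMs: earlier than the last event time")
  v
}
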