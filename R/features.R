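## The 17 hand-motor-function features and their per-task applicability.
##
## Timing conventions: the gap before the first stroke is thinking time; each
## later in-air gap (down of stroke i minus up of stroke i-1) is "unpainted
## time" charged to the *upcoming* stroke's component, reflecting planning
## before drawing that element. Pen-up strokes are internal lifts: in-air
## transitions whose flanking strokes carry the same component label.
## Painting frequency is strokes per second of on-surface time.

.strokeBits <- function(session) {
  st <- session@strokes
  t <- session@events$t
  list(comp = st$component,
       down = t[st$start],
       up = t[st$end],
       dur = t[st$end] - t[st$start])
}

#' Thinking time before the first stroke
#'
#' Time from session start (t = 0) to the first pen-down.
#'
#' @param session A [DrawingSession-class].
#' @return Milliseconds (integer).
#' @export
thinkingTime <- function(session) {
  if (!nrow(session@strokes))
    stop("feature undefined: session has no strokes", call. = FALSE)
  b <- .strokeBits(session)
  as.numeric(b$down[1])
}

.checkClass <- function(session, componentClass) {
  allowed <- taskComponents(session@taskId)
  bad <- setdiff(componentClass, allowed)
  if (length(bad))
    stop("applicability error: component class ",
         paste(bad, collapse = ", "), " not valid for task ",
         session@taskId, call. = FALSE)
  componentClass
}

#' Component painting (on-surface) time
#'
#' Sum of stroke durations over strokes whose label is in `componentClass`.
#' A class may be a single label (e.g. `"number"`) or a set (e.g. all 9
#' figure components for the figure painting time, or the global components
#' for the global drawing time).
#'
#' @param session A [DrawingSession-class].
#' @param componentClass Character vector of component labels.
#' @return Milliseconds. Zero (with attribute `no_ink = TRUE`) when the
#'   class has no strokes.
#' @export
componentPaintTime <- function(session, componentClass) {
  .checkClass(session, componentClass)
  b <- .strokeBits(session)
  sel <- b$comp %in% componentClass
  out <- sum(b$dur[sel])
  if (!any(sel)) attr(out, "no_ink") <- TRUE
  out
}

#' Component unpainted (in-air) time
#'
#' Sum of in-air gaps attributed to the class: for each stroke i >= 2 whose
#' label is in `componentClass`, the gap `down(i) - up(i-1)`. The gap before
#' the first stroke is thinking time, never unpainted time.
#'
#' @inheritParams componentPaintTime
#' @return Milliseconds.
#' @export
componentUnpaintedTime <- function(session, componentClass) {
  .checkClass(session, componentClass)
  b <- .strokeBits(session)
  n <- length(b$comp)
  if (n < 2) return(0)
  gaps <- b$down[-1] - b$up[-n]
  sel <- b$comp[-1] %in% componentClass
  sum(gaps[sel])
}

#' Component stroke counts
#'
#' `total`: number of strokes of the class. `penup`: internal pen lifts,
#' i.e. in-air transitions whose flanking strokes carry the same label, for
#' labels in the class.
#'
#' @inheritParams componentPaintTime
#' @return Named numeric `c(total=, penup=)`.
#' @export
componentStrokeCounts <- function(session, componentClass) {
  .checkClass(session, componentClass)
  b <- .strokeBits(session)
  n <- length(b$comp)
  total <- sum(b$comp %in% componentClass)
  penup <- if (n < 2) 0L else
    sum(b$comp[-1] == b$comp[-n] & b$comp[-1] %in% componentClass)
  c(total = total, penup = penup)
}

#' Painting frequency
#'
#' Strokes of the class per second of the class's on-surface time.
#'
#' @inheritParams componentPaintTime
#' @return Strokes per second.
#' @export
paintingFrequency <- function(session, componentClass) {
  paint <- componentPaintTime(session, componentClass)
  if (paint <= 0)
    stop("feature undefined: zero paint time for class ",
         paste(componentClass, collapse = "+"), call. = FALSE)
  counts <- componentStrokeCounts(session, componentClass)
  unname(counts["total"] / (paint / 1000))
}

.safeFreq <- function(session, componentClass) {
  tryCatch(paintingFrequency(session, componentClass),
           error = function(e) NA_real_)
}

#' Extract the 17-slot feature vector of a session
#'
#' Fills every slot applicable to the session's task (the non-empty cells
#' of the per-task feature matrix) and leaves the rest `NA` with
#' `applicable = FALSE`. Slot 17 is the rubric total from `scoreReport`.
#'
#' Slot meanings per family: clock drawing tasks use per-component (circle /
#' number / pointer) paint, unpainted, stroke-count and frequency slots; the
#' figure tasks use whole-figure sums; the drag task uses number and pointer
#' drag times plus the overall hand drag frequency; the point-and-line task
#' uses global and local drawing (paint) time sums and the overall drawing
#' frequency.
#'
#' @param session A [DrawingSession-class].
#' @param scoreReport The session's [ScoreReport-class] (from
#'   [scoreSession()]); `NULL` leaves slot 17 `NA`.
#' @return A [FeatureVector-class].
#' @export
extractFeatures <- function(session, scoreReport = NULL) {
  task <- .checkTaskId(session@taskId)
  fam <- .taskFamily(task)
  vals <- setNames(rep(NA_real_, 17), .FEATURE_IDS)
  app <- .APPLICABILITY[task, ]
  put <- function(slot, x) vals[[slot]] <<- as.numeric(x)

  put("f01", thinkingTime(session))
  if (fam == "clockDraw") {
    for (i in seq_along(.CLOCK_COMPONENTS)) {
      cl <- .CLOCK_COMPONENTS[i]
      put(.FEATURE_IDS[1 + i], componentPaintTime(session, cl))
      put(.FEATURE_IDS[4 + i], componentUnpaintedTime(session, cl))
      cnt <- componentStrokeCounts(session, cl)
      put(.FEATURE_IDS[7 + i], cnt["total"])
      put(.FEATURE_IDS[10 + i], cnt["penup"])
      put(.FEATURE_IDS[13 + i], .safeFreq(session, cl))
    }
  } else if (fam == "figureDraw") {
    all9 <- .FIGURE_COMPONENTS
    put("f03", componentPaintTime(session, all9))
    put("f06", componentUnpaintedTime(session, all9))
    cnt <- componentStrokeCounts(session, all9)
    put("f09", cnt["total"])
    put("f12", cnt["penup"])
    put("f15", .safeFreq(session, all9))
  } else if (fam == "clockDrag") {
    put("f02", componentPaintTime(session, "number"))
    put("f04", componentPaintTime(session, "pointer"))
    put("f14", .safeFreq(session, c("number", "pointer")))
  } else { # pointLine
    put("f05", componentPaintTime(session, .GLOBAL_COMPONENTS))
    put("f07", componentPaintTime(session, .LOCAL_COMPONENTS))
    put("f16", .safeFreq(session, .FIGURE_COMPONENTS))
  }
  if (!is.null(scoreReport)) put("f17", scoreTotal(scoreReport))
  vals[!app] <- NA_real_
  new("FeatureVector", taskId = task, values = vals, applicable = app)
}

#' Feature table for a cohort
#'
#' One row per (subject, task): `subject_id`, `task_id`, `group`,
#' `f01`..`f17` (inapplicable slots are `NA`, written as empty CSV cells).
#' Sessions are scored with [scoreSession()] on the fly.
#'
#' @param bundle A [CohortBundle-class], or a list of sessions if
#'   `subjects` is given.
#' @param subjects Optional subject `data.frame` (needed when `bundle` is a
#'   plain session list).
#' @return `data.frame` of features.
#' @export
featureTable <- function(bundle, subjects = NULL) {
  if (is(bundle, "CohortBundle")) {
    sessions <- bundle@sessions
    subjects <- bundle@subjects
  } else {
    sessions <- bundle
    if (is.null(subjects)) stop("subjects required with a session list")
  }
  rows <- lapply(sessions, function(s) {
    fv <- extractFeatures(s, scoreSession(s))
    cbind(data.frame(subject_id = s@subjectId, task_id = s@taskId,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv@values)))
  })
  out <- do.call(rbind, rows)
  out$group <- subjects$group[match(out$subject_id, subjects$subject_id)]
  out[, c("subject_id", "task_id", "group", .FEATURE_IDS)]
}

#' Per-task feature matrix for modelling
#'
#' Selects one task's rows, keeps that task's applicable feature columns,
#' and drops rows with any missing value (features undefined on the data
#' are excluded rather than imputed).
#'
#' @param featTab Output of [featureTable()].
#' @param task Task id.
#' @return List with `x` (numeric matrix, task-specific column names),
#'   `group` (factor HC/MCI), `subject_id`.
#' @export
taskFeatureMatrix <- function(featTab, task) {
  task <- .checkTaskId(task)
  sel <- featTab$task_id == task
  if (!any(sel)) stop("no rows for task ", task, call. = FALSE)
  app <- names(which(.APPLICABILITY[task, ]))
  x <- as.matrix(featTab[sel, app, drop = FALSE])
  nm <- featureNames(task)[app]
  colnames(x) <- nm
  keep <- stats::complete.cases(x)
  list(x = x[keep, , drop = FALSE],
       group = factor(featTab$group[sel][keep], levels = c("HC", "MCI")),
       subject_id = featTab$subject_id[sel][keep])
}

#' Assemble a SummarizedExperiment of one task's features
#'
#' Features x subjects assay (`"features"`), subject covariates in
#' `colData`, slot metadata (id, task-specific name, applicability) in
#' `rowData`.
#'
#' @param featTab Output of [featureTable()].
#' @param subjects Subject `data.frame`.
#' @param task Task id.
#' @return A [SummarizedExperiment::SummarizedExperiment-class].
#' @export
featureExperiment <- function(featTab, subjects, task) {
  task <- .checkTaskId(task)
  sel <- featTab$task_id == task
  if (!any(sel)) stop("no rows for task ", task, call. = FALSE)
  sub <- featTab$subject_id[sel]
  m <- t(as.matrix(featTab[sel, .FEATURE_IDS, drop = FALSE]))
  colnames(m) <- sub
  cd <- subjects[match(sub, subjects$subject_id), , drop = FALSE]
  rownames(cd) <- sub
  rd <- S4Vectors::DataFrame(
    slot = .FEATURE_IDS,
    name = unname(featureNames(task)),
    applicable = unname(.APPLICABILITY[task, ]))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = m),
    rowData = rd,
    colData = S4Vectors::DataFrame(cd),
    metadata = list(task = taskInfo(task)))
}
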