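#' @import methods
#' @importFrom stats rlnorm rpois rbinom rnorm runif median quantile
#'   wilcox.test t.test chisq.test cor.test glm binomial pchisq qnorm
#'   predict coef logLik setNames aggregate
#' @importFrom utils read.csv write.csv
NULL

.PHASES <- c("down", "move", "up")
.SOURCES <- c("stylus", "drag")

## ---------------------------------------------------------------------------
## DrawingSession: one subject x task event stream, its stroke segmentation
## and the structured scoring annotation.
## ---------------------------------------------------------------------------

#' DrawingSession class
#'
#' One digitized session: the timestamped pen/drag event stream of a subject
#' performing one task, its segmentation into component-labelled strokes, and
#' the structured annotation from which the task rubric is scored.
#'
#' @slot subjectId Opaque subject identifier.
#' @slot taskId Task id, `"T1"`..`"T8"`.
#' @slot events `data.frame` with columns `t` (integer ms since session
#'   start), `x`, `y` (device pixels, top-left origin), `phase`
#'   (`down`/`move`/`up`) and `source` (`stylus`/`drag`).
#' @slot strokes `data.frame` with columns `component`, `start`, `end`
#'   (1-based inclusive event indices of each down..up run, in temporal
#'   order).
#' @slot annotation Named list; structure depends on the task family (see
#'   [scoreSession()]).
#' @slot sessionEndMs Integer, at least the time of the last event.
#'
#' @seealso [drawingSession()], [validateSession()], [extractFeatures()]
#' @export
setClass("DrawingSession", slots = c(
  subjectId = "character",
  taskId = "character",
  events = "data.frame",
  strokes = "data.frame",
  annotation = "list",
  sessionEndMs = "integer"
))

setValidity("DrawingSession", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L) msg <- c(msg, "subjectId must be length 1")
  if (length(object@taskId) != 1L) msg <- c(msg, "taskId must be length 1")
  need <- c("t", "x", "y", "phase", "source")
  if (!all(need %in% names(object@events)))
    msg <- c(msg, paste("events must have columns", paste(need, collapse = ", ")))
  if (!all(c("component", "start", "end") %in% names(object@strokes)))
    msg <- c(msg, "strokes must have columns component, start, end")
  if (length(object@sessionEndMs) != 1L)
    msg <- c(msg, "sessionEndMs must be length 1")
  if (length(msg)) msg else TRUE
})

#' Construct a DrawingSession
#'
#' Validates structural requirements; semantic invariants (event ordering,
#' phase legality, label sets, timeline bounds) are checked by
#' [validateSession()], which the constructor applies with `strict = TRUE`.
#'
#' @param subjectId Subject identifier.
#' @param taskId Task id (`"T1"`..`"T8"`).
#' @param events Event `data.frame` (`t`, `x`, `y`, `phase`, `source`).
#' @param strokes Stroke `data.frame` (`component`, `start`, `end`). If
#'   `NULL`, strokes are segmented from the events and all get component
#'   label `NA` (useful for unannotated streams in tests).
#' @param annotation Named list of scoring annotations (may be empty).
#' @param sessionEndMs Session end time; defaults to the last event time.
#' @param strict If `TRUE` (default), any invariant violation is an error.
#' @return A [DrawingSession-class] object.
#' @export
#' @examples
#' ev <- data.frame(t = c(0L, 50L, 100L), x = 0L, y = 0L,
#'                  phase = c("down", "move", "up"), source = "stylus")
#' s <- drawingSession("s1", "T5", ev,
#'                     strokes = data.frame(component = "global_1",
#'                                          start = 1L, end = 3L))
#' strokeDurations(s)
drawingSession <- function(subjectId, taskId, events, strokes = NULL,
                           annotation = list(), sessionEndMs = NULL,
                           strict = TRUE) {
  events <- as.data.frame(events)
  events$t <- as.integer(events$t)
  events$x <- as.integer(round(events$x))
  events$y <- as.integer(round(events$y))
  events$phase <- as.character(events$phase)
  events$source <- as.character(events$source)
  if (is.null(strokes)) {
    seg <- segmentStrokes(events)
    strokes <- data.frame(component = rep(NA_character_, nrow(seg)),
                          start = seg$start, end = seg$end)
  }
  strokes <- as.data.frame(strokes)
  strokes$component <- as.character(strokes$component)
  strokes$start <- as.integer(strokes$start)
  strokes$end <- as.integer(strokes$end)
  if (is.null(sessionEndMs)) {
    sessionEndMs <- if (nrow(events)) max(events$t) else 0L
  }
  obj <- new("DrawingSession", subjectId = as.character(subjectId),
             taskId = as.character(taskId), events = events,
             strokes = strokes, annotation = annotation,
             sessionEndMs = as.integer(sessionEndMs))
  if (strict) {
    v <- validateSession(obj)
    if (length(v)) stop("invalid session: ", paste(v, collapse = "; "),
                        call. = FALSE)
  }
  obj
}

#' @describeIn DrawingSession-class subject identifier accessor
#' @param object,x A `DrawingSession`.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @export
setMethod("subjectId", "DrawingSession", function(x) x@subjectId)

#' @export
setGeneric("taskId", function(x) standardGeneric("taskId"))
#' @export
setMethod("taskId", "DrawingSession", function(x) x@taskId)

#' @export
setGeneric("penEvents", function(x) standardGeneric("penEvents"))
#' @export
setMethod("penEvents", "DrawingSession", function(x) x@events)

#' @export
setGeneric("strokeTable", function(x) standardGeneric("strokeTable"))
#' @export
setMethod("strokeTable", "DrawingSession", function(x) x@strokes)

#' @export
setGeneric("annotation", function(x) standardGeneric("annotation"))
#' @export
setMethod("annotation", "DrawingSession", function(x) x@annotation)

#' @export
setGeneric("sessionEnd", function(x) standardGeneric("sessionEnd"))
#' @export
setMethod("sessionEnd", "DrawingSession", function(x) x@sessionEndMs)

#' Stroke durations of a session
#'
#' @param x A `DrawingSession`.
#' @return Integer vector, `t(up) - t(down)` per stroke in temporal order.
#' @export
strokeDurations <- function(x) {
  st <- x@strokes
  if (!nrow(st)) return(integer())
  as.integer(x@events$t[st$end] - x@events$t[st$start])
}

setMethod("show", "DrawingSession", function(object) {
  cat("DrawingSession", object@subjectId, "/", object@taskId,
      sprintf("(%s)\n", .TASK_TABLE$name[.TASK_TABLE$task_id == object@taskId]))
  cat("  ", nrow(object@events), "events,", nrow(object@strokes),
      "strokes, ends at", object@sessionEndMs, "ms\n")
})

## ---------------------------------------------------------------------------
## EffectConfig / CohortBundle: synthetic cohort generation
## ---------------------------------------------------------------------------

#' EffectConfig class
#'
#' Group-level generative settings for the synthetic cohort: log-normal
#' timing distributions (thinking time, on-surface stroke duration,
#' inter-stroke in-air gap), potential sub-strokes per component, internal
#' pen-lift probability, a drawing-quality propensity driving rubric
#' sub-scores, and cohort sizes.
#'
#' @slot hc,mci Named parameter lists per group (see [effectConfig()]).
#' @slot scoreShift Additive shift (rubric points, on the 0-18 figure scale)
#'   applied to the MCI group's expected score.
#' @slot nPerGroup Named integer vector `c(HC = ..., MCI = ...)`.
#' @slot seed Integer base seed.
#' @export
setClass("EffectConfig", slots = c(
  hc = "list", mci = "list", scoreShift = "numeric",
  nPerGroup = "integer", seed = "integer"
))

setValidity("EffectConfig", function(object) {
  msg <- character()
  for (g in c("hc", "mci")) {
    p <- slot(object, g)
    med <- unlist(p[c("think_median", "stroke_median", "air_median")])
    if (any(!is.finite(med)) || any(med <= 0))
      msg <- c(msg, paste0(g, ": timing medians must be > 0"))
    if (p$internal_lift_prob < 0 || p$internal_lift_prob > 1)
      msg <- c(msg, paste0(g, ": internal_lift_prob must be in [0,1]"))
    if (p$quality < 0 || p$quality > 1)
      msg <- c(msg, paste0(g, ": quality must be in [0,1]"))
    if (p$strokes_per_component < 1)
      msg <- c(msg, paste0(g, ": strokes_per_component must be >= 1"))
  }
  if (any(object@nPerGroup < 2L)) msg <- c(msg, "nPerGroup must be >= 2")
  if (!identical(sort(names(object@nPerGroup)), c("HC", "MCI")))
    msg <- c(msg, "nPerGroup must be named HC, MCI")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EffectConfig", function(object) {
  cat("EffectConfig: n =", object@nPerGroup[["HC"]], "HC /",
      object@nPerGroup[["MCI"]], "MCI, seed", object@seed, "\n")
  for (g in c("hc", "mci")) {
    p <- slot(object, g)
    cat(sprintf("  %-3s think %g ms, stroke %g ms, air %g ms, lift p %.2f, quality %.2f\n",
                toupper(g), p$think_median, p$stroke_median, p$air_median,
                p$internal_lift_prob, p$quality))
  }
  cat("  score shift (MCI):", object@scoreShift, "\n")
})

#' CohortBundle class
#'
#' A generated cohort: the subject table, one [DrawingSession-class] per
#' subject per task, and the [EffectConfig-class] that produced them.
#'
#' @slot subjects `data.frame` of subject covariates (one row per subject).
#' @slot sessions List of `DrawingSession` objects (8 per subject).
#' @slot config The generating `EffectConfig`.
#' @export
setClass("CohortBundle", slots = c(
  subjects = "data.frame", sessions = "list", config = "EffectConfig"
))

setMethod("show", "CohortBundle", function(object) {
  cat("CohortBundle:", nrow(object@subjects), "subjects (",
      sum(object@subjects$group == "HC"), "HC /",
      sum(object@subjects$group == "MCI"), "MCI ),",
      length(object@sessions), "sessions\n")
})

#' @export
setGeneric("cohortSubjects", function(x) standardGeneric("cohortSubjects"))
#' @export
setMethod("cohortSubjects", "CohortBundle", function(x) x@subjects)

#' @export
setGeneric("cohortSessions", function(x) standardGeneric("cohortSessions"))
#' @export
setMethod("cohortSessions", "CohortBundle", function(x) x@sessions)

#' @export
setGeneric("cohortConfig", function(x) standardGeneric("cohortConfig"))
#' @export
setMethod("cohortConfig", "CohortBundle", function(x) x@config)

## ---------------------------------------------------------------------------
## ScoreReport
## ---------------------------------------------------------------------------

#' ScoreReport class
#'
#' Output of a rubric scorer: the total and the per-component sub-scores.
#' Rubrics: `schulman` (clock severity, 1 best to 6 worst), `srcft`
#' (9-component figure score, 0-18 in 0.5 steps, higher better), `dragclock`
#' (0-3, one point per satisfied criterion).
#'
#' @slot taskId Task id (may be `NA` when scoring a bare annotation).
#' @slot rubric One of `"schulman"`, `"srcft"`, `"dragclock"`.
#' @slot total Numeric total score.
#' @slot perComponent `data.frame` with columns `component`, `score`.
#' @export
setClass("ScoreReport", slots = c(
  taskId = "character", rubric = "character", total = "numeric",
  perComponent = "data.frame"
))

setValidity("ScoreReport", function(object) {
  msg <- character()
  tot <- object@total
  ok <- switch(object@rubric,
    schulman = tot %in% 1:6,
    srcft = tot >= 0 && tot <= 18 && isTRUE(all.equal(tot * 2, round(tot * 2))),
    dragclock = tot %in% 0:3,
    FALSE)
  if (!isTRUE(ok))
    msg <- c(msg, paste0("total ", tot, " outside range of rubric ",
                         object@rubric))
  if (length(msg)) msg else TRUE
})

#' @export
setGeneric("scoreTotal", function(x) standardGeneric("scoreTotal"))
#' @export
setMethod("scoreTotal", "ScoreReport", function(x) x@total)

setMethod("show", "ScoreReport", function(object) {
  cat("ScoreReport [", object@rubric, "] total =", object@total, "\n")
  if (nrow(object@perComponent))
    cat("  components:", paste(sprintf("%s=%g", object@perComponent$component,
                                       object@perComponent$score),
                               collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## GroupComparison
## ---------------------------------------------------------------------------

#' GroupComparison class
#'
#' One feature's two-group comparison: per-group Lilliefors normality p
#' values, the normality-gated test used (Welch/pooled t, or Mann-Whitney),
#' its statistic and two-sided p, and the Hodges-Lehmann location-shift
#' estimate (MCI minus HC) with a distribution-free 95% CI.
#'
#' @slot feature Feature identifier.
#' @slot nHC,nMCI Group sizes.
#' @slot normalityP Named numeric `c(HC=, MCI=)`.
#' @slot testUsed `"t"` or `"mann_whitney"`.
#' @slot statistic t or z statistic.
#' @slot pValue Two-sided p value.
#' @slot hlEstimate Hodges-Lehmann shift estimate.
#' @slot hlCI Numeric length 2, 95% CI.
#' @slot significant Logical, `pValue < alpha`.
#' @slot alpha Significance level used.
#' @export
setClass("GroupComparison", slots = c(
  feature = "character", nHC = "integer", nMCI = "integer",
  normalityP = "numeric", testUsed = "character", statistic = "numeric",
  pValue = "numeric", hlEstimate = "numeric", hlCI = "numeric",
  significant = "logical", alpha = "numeric"
))

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf(
    "GroupComparison %s: %s, stat=%.3f, p=%.4g, HL=%.3f [%.3f, %.3f]%s\n",
    object@feature, object@testUsed, object@statistic, object@pValue,
    object@hlEstimate, object@hlCI[1], object@hlCI[2],
    if (object@significant) " *" else ""))
})

## ---------------------------------------------------------------------------
## StepwiseModel / DiagnosticPerformance
## ---------------------------------------------------------------------------

#' StepwiseModel class
#'
#' A forward-stepwise logistic diagnostic model: the ordered selected
#' features, their coefficients with odds ratios and Wald 95% CIs, the entry
#' and removal thresholds used, and a fit log of every step.
#'
#' @slot taskId Task id (or `NA`).
#' @slot selected Ordered character vector of selected features.
#' @slot coefTable `data.frame`: `term`, `beta`, `se`, `or`, `or_lo`,
#'   `or_hi`, `p` (Wald), excluding the intercept.
#' @slot intercept Numeric intercept.
#' @slot entryP,removalP Likelihood-ratio entry/removal p thresholds.
#' @slot fitLog Character vector narrating each step.
#' @slot fit The final `glm` fit (intercept-only if nothing entered).
#' @export
setClass("StepwiseModel", slots = c(
  taskId = "character", selected = "character", coefTable = "data.frame",
  intercept = "numeric", entryP = "numeric", removalP = "numeric",
  fitLog = "character", fit = "ANY"
))

setMethod("show", "StepwiseModel", function(object) {
  cat("StepwiseModel", object@taskId, "- selected:",
      if (length(object@selected)) paste(object@selected, collapse = ", ")
      else "(none)", "\n")
  if (nrow(object@coefTable)) {
    with(object@coefTable, cat(sprintf(
      "  %-28s beta=%7.3f OR=%6.3f (%5.3f-%6.3f) p=%.4g\n",
      term, beta, or, or_lo, or_hi, p), sep = ""))
  }
})

#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))
#' @export
setMethod("selectedFeatures", "StepwiseModel", function(x) x@selected)

#' @export
setGeneric("coefTable", function(x) standardGeneric("coefTable"))
#' @export
setMethod("coefTable", "StepwiseModel", function(x) x@coefTable)

#' DiagnosticPerformance class
#'
#' Classification performance of a diagnostic model at a probability
#' threshold: the confusion matrix (MCI = positive class), accuracy,
#' sensitivity, specificity, AUC with DeLong 95% CI, and the ROC curve.
#'
#' @slot accuracy,sensitivity,specificity Proportions in `[0, 1]`.
#' @slot auc AUC (may be `NA` for confusion-only summaries).
#' @slot aucCI Numeric length 2 (DeLong), `NA` when unavailable.
#' @slot roc `data.frame` with columns `fpr`, `tpr`, from (0,0) to (1,1).
#' @slot confusion Named numeric `c(tp=, fn=, tn=, fp=)`.
#' @slot threshold Probability threshold used.
#' @export
setClass("DiagnosticPerformance", slots = c(
  accuracy = "numeric", sensitivity = "numeric", specificity = "numeric",
  auc = "numeric", aucCI = "numeric", roc = "data.frame",
  confusion = "numeric", threshold = "numeric"
))

setValidity("DiagnosticPerformance", function(object) {
  msg <- character()
  cf <- object@confusion
  if (!identical(sort(names(cf)), c("fn", "fp", "tn", "tp")))
    msg <- c(msg, "confusion must be named tp, fn, tn, fp")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DiagnosticPerformance", function(object) {
  cat(sprintf(
    "DiagnosticPerformance: acc=%.3f sens=%.3f spec=%.3f auc=%s\n",
    object@accuracy, object@sensitivity, object@specificity,
    if (is.na(object@auc)) "NA"
    else sprintf("%.3f (%.3f-%.3f)", object@auc, object@aucCI[1],
                 object@aucCI[2])))
})

## ---------------------------------------------------------------------------
## FeatureVector / PseudocolorImage
## ---------------------------------------------------------------------------

#' FeatureVector class
#'
#' The 17 hand-motor-function feature slots of one session. Inapplicable
#' slots (empty cells of the per-task feature matrix) are `NA` with
#' `applicable = FALSE`; an applicable slot is `NA` only when undefined on
#' the data (e.g. a frequency with zero paint time).
#'
#' @slot taskId Task id.
#' @slot values Named numeric length 17 (`f01`..`f17`). Times in ms, counts,
#'   frequencies in strokes/s, slot 17 in rubric units.
#' @slot applicable Named logical length 17.
#' @export
setClass("FeatureVector", slots = c(
  taskId = "character", values = "numeric", applicable = "logical"
))

setValidity("FeatureVector", function(object) {
  msg <- character()
  if (length(object@values) != 17L || length(object@applicable) != 17L)
    msg <- c(msg, "values and applicable must have length 17")
  if (any(!is.na(object@values) & !object@applicable))
    msg <- c(msg, "inapplicable slots must be NA")
  if (length(msg)) msg else TRUE
})

#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @export
setMethod("featureValues", "FeatureVector", function(x) x@values)

setMethod("show", "FeatureVector", function(object) {
  nm <- featureNames(object@taskId)
  app <- which(object@applicable)
  cat("FeatureVector", object@taskId, "(", length(app), "applicable slots )\n")
  for (i in app)
    cat(sprintf("  %s %-28s %s\n", names(object@values)[i], nm[i],
                format(object@values[i])))
})

#' PseudocolorImage class
#'
#' A stroke-order pseudocolor rendering: an RGB raster in which each stroke
#' polyline is drawn in a color determined solely by its index within the
#' session, later strokes overdrawing earlier ones.
#'
#' @slot raster Numeric array `height x width x 3`, values in `[0, 1]`.
#' @slot colors Hex color legend, one entry per stroke in stroke order.
#' @slot width,height Raster dimensions in pixels.
#' @export
setClass("PseudocolorImage", slots = c(
  raster = "array", colors = "character", width = "integer",
  height = "integer"
))

setMethod("show", "PseudocolorImage", function(object) {
  cat("PseudocolorImage", object@width, "x", object@height, "px,",
      length(object@colors), "strokes\n")
})
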