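## Task registry: the eight tablet tasks, their component label sets, rubric
## family, and the 17-slot feature applicability matrix.

.GLOBAL_COMPONENTS <- paste0("global_", 1:5)
.LOCAL_COMPONENTS <- paste0("local_", 1:4)
.FIGURE_COMPONENTS <- c(.GLOBAL_COMPONENTS, .LOCAL_COMPONENTS)
.CLOCK_COMPONENTS <- c("circle", "number", "pointer")

.FEATURE_IDS <- sprintf("f%02d", 1:17)

## One row per task. family drives feature definitions, scoring and the
## generator's component sequence; rubric names the scorer used for slot 17.
.TASK_TABLE <- data.frame(
  task_id = paste0("T", 1:8),
  name = c(
    "dCDT single task",
    "dCDT dual task (series 1)",
    "dCDT dual task (animal names)",
    "dCDT dual task (series 3)",
    "sRCFT raw copy",
    "sRCFT delayed recall",
    "clock drag and drop",
    "sRCFT point and line"
  ),
  family = c(rep("clockDraw", 4), "figureDraw", "figureDraw",
             "clockDrag", "pointLine"),
  rubric = c(rep("schulman", 4), "srcft", "srcft", "dragclock", "srcft"),
  stringsAsFactors = FALSE
)

## Feature applicability: non-empty cells of the published per-task feature
## matrix. Clock drawing tasks use all 17 slots; the figure tasks and the two
## dragging tasks use subsets.
.APPLICABILITY <- {
  m <- matrix(FALSE, nrow = 8, ncol = 17,
              dimnames = list(.TASK_TABLE$task_id, .FEATURE_IDS))
  m[c("T1", "T2", "T3", "T4"), ] <- TRUE
  m[c("T5", "T6"), c(1, 3, 6, 9, 12, 15, 17)] <- TRUE
  m["T7", c(1, 2, 4, 14, 17)] <- TRUE
  m["T8", c(1, 5, 7, 16, 17)] <- TRUE
  m
}

## Slot names per task family. Shared slots keep one name; slots whose
## meaning depends on the family (e.g. slot 2 is circle painting time for a
## drawn clock but number drag time for the drag task) are renamed here.
.FEATURE_NAMES <- list(
  clockDraw = c(
    "thinking_time_first_stroke", "circle_paint_time", "number_paint_time",
    "pointer_paint_time", "circle_unpainted_time", "number_unpainted_time",
    "pointer_unpainted_time", "circle_total_stroke", "number_total_stroke",
    "pointer_total_stroke", "circle_penup_stroke", "number_penup_stroke",
    "pointer_penup_stroke", "circle_paint_freq", "number_paint_freq",
    "pointer_paint_freq", "score"),
  figureDraw = c(
    "thinking_time_first_stroke", NA, "figure_paint_time", NA, NA,
    "figure_unpainted_time", NA, NA, "figure_total_stroke", NA, NA,
    "figure_penup_stroke", NA, NA, "figure_paint_freq", NA, "score"),
  clockDrag = c(
    "thinking_time_first_stroke", "number_drag_time", NA,
    "pointer_drag_time", NA, NA, NA, NA, NA, NA, NA, NA, NA,
    "hand_drag_freq", NA, NA, "score"),
  pointLine = c(
    "thinking_time_first_stroke", NA, NA, NA, "global_drawing_time", NA,
    "local_drawing_time", NA, NA, NA, NA, NA, NA, NA, NA,
    "figure_draw_freq", "score")
)

#' Task identifiers
#'
#' @return Character vector `"T1"` to `"T8"`.
#' @export
#' @examples
#' taskIds()
taskIds <- function() .TASK_TABLE$task_id

#' Describe a task
#'
#' Returns the registry row for a task: its descriptive name, task family,
#' rubric, and permitted component labels.
#'
#' @param task Task id, one of `taskIds()`.
#' @return A list with elements `task_id`, `name`, `family`, `rubric`,
#'   `components`.
#' @export
#' @examples
#' taskInfo("T5")$components
taskInfo <- function(task) {
  task <- .checkTaskId(task)
  row <- .TASK_TABLE[.TASK_TABLE$task_id == task, ]
  list(task_id = task, name = row$name, family = row$family,
       rubric = row$rubric, components = taskComponents(task))
}

#' Permitted component labels for a task
#'
#' Clock drawing tasks use `circle`, `number`, `pointer`; the figure tasks
#' (drawn or point-and-line) use the 5 global and 4 local figure components;
#' the drag task uses `number` and `pointer` only (the clock face is given,
#' not dragged).
#'
#' @inheritParams taskInfo
#' @return Character vector of component labels.
#' @export
taskComponents <- function(task) {
  task <- .checkTaskId(task)
  switch(.taskFamily(task),
    clockDraw = .CLOCK_COMPONENTS,
    figureDraw = .FIGURE_COMPONENTS,
    pointLine = .FIGURE_COMPONENTS,
    clockDrag = c("number", "pointer"))
}

#' Feature applicability mask
#'
#' Which of the 17 feature slots are defined for a task. Inapplicable slots
#' correspond to empty cells of the per-task feature matrix and are reported
#' as missing, never zero.
#'
#' @param task Task id, or `NULL` for the full 8 x 17 logical matrix.
#' @return Named logical vector of length 17, or the full matrix.
#' @export
#' @examples
#' names(which(featureApplicability("T7")))
featureApplicability <- function(task = NULL) {
  if (is.null(task)) return(.APPLICABILITY)
  .APPLICABILITY[.checkTaskId(task), ]
}

#' Task-specific feature slot names
#'
#' @inheritParams taskInfo
#' @return Character vector of length 17 named by slot id (`f01`..`f17`);
#'   `NA` for slots the task does not use.
#' @export
featureNames <- function(task) {
  task <- .checkTaskId(task)
  out <- .FEATURE_NAMES[[.taskFamily(task)]]
  names(out) <- .FEATURE_IDS
  out
}

.taskFamily <- function(task) {
  .TASK_TABLE$family[.TASK_TABLE$task_id == task]
}

.checkTaskId <- function(task) {
  if (length(task) != 1L || !is.character(task) ||
      !(task %in% .TASK_TABLE$task_id)) {
    stop("unknown task_id: ", paste(task, collapse = ", "),
         " (expected one of ", paste(.TASK_TABLE$task_id, collapse = ", "),
         ")", call. = FALSE)
  }
  task
}
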