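## Deterministic rubric scorers over structured drawing annotations.
## Scoring consumes annotations, not raw ink: for real data a clinician
## supplies the flags; the synthetic generator emits them so that every
## scorer is exercised end to end.

#' Score a 9-component figure annotation (0-18)
#'
#' Component weights: 2 when accurately drawn and correctly located; 1 when
#' exactly one of accuracy/location holds; 0.5 when neither holds but the
#' component is identifiable; 0 otherwise. Identifiability is only consulted
#' when both accuracy and location fail. The total over the 9 equally
#' weighted components ranges 0 to 18 in steps of 0.5; higher is better.
#' Used by the figure copy, delayed-recall and point-and-line tasks (the
#' point-and-line task shares the rule unchanged).
#'
#' @param annotation `data.frame` with one row per component: `component`,
#'   `accurately_drawn`, `correctly_located`, `identifiable` (logicals),
#'   covering all 9 components (`global_1`..`global_5`, `local_1`..
#'   `local_4`).
#' @param taskId Optional task id recorded in the report.
#' @return A [ScoreReport-class] with rubric `"srcft"`.
#' @export
#' @examples
#' ann <- data.frame(component = c(paste0("global_", 1:5), paste0("local_", 1:4)),
#'                   accurately_drawn = TRUE, correctly_located = TRUE,
#'                   identifiable = TRUE)
#' scoreTotal(scoreSRCFT(ann))  # 18
scoreSRCFT <- function(annotation, taskId = NA_character_) {
  annotation <- as.data.frame(annotation)
  need <- c("component", "accurately_drawn", "correctly_located",
            "identifiable")
  if (!all(need %in% names(annotation)))
    stop("annotation error: figure annotation needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  miss <- setdiff(.FIGURE_COMPONENTS, annotation$component)
  if (length(miss))
    stop("annotation error: missing component entr",
         if (length(miss) > 1) "ies " else "y ",
         paste(miss, collapse = ", "), call. = FALSE)
  annotation <- annotation[match(.FIGURE_COMPONENTS, annotation$component), ]
  acc <- as.logical(annotation$accurately_drawn)
  loc <- as.logical(annotation$correctly_located)
  idf <- as.logical(annotation$identifiable)
  sub <- ifelse(acc & loc, 2,
         ifelse(acc | loc, 1,
         ifelse(idf, 0.5, 0)))
  new("ScoreReport", taskId = taskId, rubric = "srcft", total = sum(sub),
      perComponent = data.frame(component = annotation$component,
                                score = sub))
}

## Schulman severity ladder (1 best .. 6 worst). The published criteria are
## cited, not reprinted, in the source material for this rubric; the ladder
## below fixes the tier boundaries and is kept in one place for revision.
## A "number fault" is a missing digit or a present digit out of position.
##
##  tier | condition (first match wins, checked 6 -> 1)
##  -----+---------------------------------------------------------------
##    6  | clock not recognizable
##    5  | severe disorganization: more than 6 number faults
##    4  | moderate disorganization: any order fault, or >2 number faults
##    3  | hands major error (time misrepresented), layout intact
##    2  | minor errors: 1-2 number faults, hands minor error, or contour
##       | unacceptable
##    1  | perfect clock
.SCHULMAN_LADDER <- c(
  "6: no identifiable clock",
  "5: >6 number faults (largely misplaced/missing)",
  "4: order fault or >2 number faults",
  "3: hands major error",
  "2: 1-2 number faults, hands minor error, or contour fault",
  "1: perfect")

#' Score a clock-drawing annotation on the Schulman scale (1-6)
#'
#' Ordinal severity from 1 (perfectly accomplished clock) to 6 (no
#' identifiable clock), assigned by a fixed tier ladder documented in the
#' package source (`.SCHULMAN_LADDER`): unrecognizable clocks score 6;
#' more than 6 missing/misplaced numbers scores 5; any out-of-order number
#' or more than 2 number faults scores 4; a major hand error with intact
#' layout scores 3; one or two number faults, a minor hand error or an
#' unacceptable contour scores 2; otherwise 1.
#'
#' @param annotation List with fields `contour_acceptable` (logical),
#'   `numbers` (`data.frame` with 12 rows: `digit`, `present`, `in_order`,
#'   `position_ok`), `hands_indicate_11_10` (`"correct"`, `"minor_error"`,
#'   `"major_error"`), `clock_recognizable` (logical).
#' @param taskId Optional task id recorded in the report.
#' @return A [ScoreReport-class] with rubric `"schulman"`.
#' @export
scoreClockSchulman <- function(annotation, taskId = NA_character_) {
  need <- c("contour_acceptable", "numbers", "hands_indicate_11_10",
            "clock_recognizable")
  miss <- setdiff(need, names(annotation))
  if (length(miss))
    stop("annotation error: clock annotation missing field(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  num <- as.data.frame(annotation$numbers)
  if (!all(c("present", "in_order", "position_ok") %in% names(num)) ||
      nrow(num) != 12L)
    stop("annotation error: numbers must have 12 rows with present, ",
         "in_order, position_ok", call. = FALSE)
  hands <- match.arg(annotation$hands_indicate_11_10,
                     c("correct", "minor_error", "major_error"))
  present <- as.logical(num$present)
  numberFaults <- sum(!present | (present & !as.logical(num$position_ok)))
  orderFaults <- sum(present & !as.logical(num$in_order))
  total <-
    if (!isTRUE(annotation$clock_recognizable)) 6L
    else if (numberFaults > 6L) 5L
    else if (orderFaults > 0L || numberFaults > 2L) 4L
    else if (hands == "major_error") 3L
    else if (numberFaults > 0L || hands == "minor_error" ||
             !isTRUE(annotation$contour_acceptable)) 2L
    else 1L
  new("ScoreReport", taskId = taskId, rubric = "schulman",
      total = as.numeric(total),
      perComponent = data.frame(
        component = c("number_faults", "order_faults"),
        score = c(numberFaults, orderFaults)))
}

#' Score a clock drag-and-drop annotation (0-3)
#'
#' One point per satisfied criterion: numbers position, numbers order, and
#' pointers indicating 11:10. A high score indicates a perfect clock.
#'
#' @param annotation List with logical fields `numbers_position_ok`,
#'   `numbers_order_ok`, `pointers_ok`.
#' @param taskId Optional task id recorded in the report.
#' @return A [ScoreReport-class] with rubric `"dragclock"`.
#' @export
scoreDragClock <- function(annotation, taskId = NA_character_) {
  need <- c("numbers_position_ok", "numbers_order_ok", "pointers_ok")
  miss <- setdiff(need, names(annotation))
  if (length(miss))
    stop("annotation error: drag annotation missing field(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  flags <- vapply(annotation[need], isTRUE, logical(1))
  new("ScoreReport", taskId = taskId, rubric = "dragclock",
      total = as.numeric(sum(flags)),
      perComponent = data.frame(component = need, score = as.numeric(flags)))
}

#' Score a session with its task's rubric
#'
#' Dispatches on the task family: Schulman for the clock drawing tasks,
#' the 0-18 component score for the figure tasks (including point-and-line),
#' and the 0-3 additive rubric for the drag task.
#'
#' @param session A [DrawingSession-class] carrying its annotation.
#' @return A [ScoreReport-class].
#' @export
scoreSession <- function(session) {
  task <- .checkTaskId(session@taskId)
  switch(.TASK_TABLE$rubric[.TASK_TABLE$task_id == task],
    srcft = scoreSRCFT(session@annotation$components, task),
    schulman = scoreClockSchulman(session@annotation, task),
    dragclock = scoreDragClock(session@annotation, task))
}
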