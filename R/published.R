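## Published reference tables bundled with the package. They summarize a
## 207-participant clinical cohort (99 healthy controls, 108 MCI) evaluated
## with this feature catalog and these rubrics, and serve as inputs for
## worked examples and arithmetic consistency checks; the underlying raw
## pen data are not publicly deposited, so cohort-level results are not
## recomputable from ink.

.extdata <- function(name) {
  system.file("extdata", name, package = "inkcog", mustWork = TRUE)
}

#' Published per-task feature-screen p values
#'
#' The 8 x 17 grid of two-group p values (one row per task, one column per
#' feature slot) as printed for the reference cohort; censored entries are
#' kept verbatim (`"<.001"`) and empty cells mark inapplicable slots. Use
#' [parsePValue()] before filtering with [significantFeatures()].
#'
#' @return `data.frame` with `task_id` and character columns `f01`..`f17`.
#' @export
#' @examples
#' pv <- publishedFeaturePValues()
#' length(significantFeatures(parsePValue(
#'   setNames(unlist(pv[pv$task_id == "T1", -1]), names(pv)[-1]))))
publishedFeaturePValues <- function() {
  read.csv(.extdata("published_feature_pvalues.csv"),
           colClasses = "character", check.names = FALSE)
}

#' Published per-task diagnostic performance
#'
#' Accuracy, sensitivity, specificity and AUC (with 95% CI) of the six
#' reference diagnostic models, with each model tagged as a drawing or a
#' dragging task.
#'
#' @return `data.frame` with columns `model`, `type`, `accuracy`,
#'   `sensitivity`, `specificity`, `auc`, `auc_lo`, `auc_hi`.
#' @export
publishedTaskPerformance <- function() {
  read.csv(.extdata("published_task_performance.csv"),
           stringsAsFactors = FALSE)
}

#' Published confusion counts
#'
#' The confusion counts reported for the two headline reference models
#' (MCI positive): the dual-task clock model (95/108 sensitivity) and the
#' figure delayed-recall model (183/207 accuracy, 90/99 specificity).
#'
#' @return `data.frame` with columns `model`, `tp`, `fn`, `tn`, `fp`.
#' @export
publishedConfusionCounts <- function() {
  read.csv(.extdata("published_confusion_counts.csv"),
           stringsAsFactors = FALSE)
}
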