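## End-to-end orchestration: simulate -> score -> extract -> stats ->
## classify -> render, writing the analysis output tables (feature p-value
## grid, long comparisons, model coefficients, per-task performance,
## cross-task averages) and a manifest of every artifact.

#' Run the full analysis pipeline
#'
#' Generates (or reuses) a synthetic cohort, writes the session and cohort
#' files, scores every session, extracts the feature table, runs the
#' per-task two-group feature screen, fits the per-task forward-stepwise
#' diagnostic models with their performance metrics and cross-task
#' averages, renders one pseudocolor example per group, and writes a
#' manifest with an MD5 hash per artifact. Deterministic given the config
#' seed.
#'
#' @param config An [EffectConfig-class].
#' @param outDir Output directory (created if missing).
#' @param tasks Task subset (default all 8).
#' @param alpha Significance level for the feature screen.
#' @param entryP,removalP Stepwise entry/removal thresholds.
#' @param threshold Classification probability threshold.
#' @param render Render example pseudocolor images (default `TRUE`).
#' @param verbose Narrate stages with `message()`.
#' @return Invisibly, a list with `manifest` (`data.frame` of file, md5),
#'   `featureTable`, `comparisons`, `models`, `performance`, `averages`.
#' @export
#' @examples
#' \donttest{
#' res <- runPipeline(effectConfig("null", nPerGroup = c(HC = 8, MCI = 8)),
#'                    outDir = tempfile(), tasks = c("T5", "T7"))
#' res$performance
#' }
runPipeline <- function(config = effectConfig(), outDir = "inkcog-out",
                        tasks = taskIds(), alpha = 0.05, entryP = 0.05,
                        removalP = 0.10, threshold = 0.5, render = TRUE,
                        verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  stopifnot(threshold > 0, threshold < 1, entryP >= 0, entryP <= 1)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  emit <- function(name) {
    p <- file.path(outDir, name)
    paths <<- c(paths, p)
    p
  }
  stage <- "simulate"
  res <- tryCatch({
    say("[simulate] generating cohort (seed ", config@seed, ")")
    bundle <- generateCohort(config, tasks,
                             sessionsPath = emit("sessions.jsonl"),
                             cohortPath = emit("subjects.csv"))

    stage <- "score"
    say("[score] scoring ", length(bundle@sessions), " sessions")
    scores <- do.call(rbind, lapply(bundle@sessions, function(s) {
      rep <- scoreSession(s)
      data.frame(subject_id = s@subjectId, task_id = s@taskId,
                 rubric = rep@rubric, total = rep@total,
                 stringsAsFactors = FALSE)
    }))
    write.csv(scores, emit("scores.csv"), row.names = FALSE)

    stage <- "extract"
    say("[extract] building the feature table")
    featTab <- featureTable(bundle)
    write.csv(featTab, emit("features.csv"), row.names = FALSE, na = "")

    stage <- "stats"
    say("[stats] two-group feature screen (alpha = ", alpha, ")")
    comparisons <- do.call(rbind, lapply(tasks, function(tk)
      compareAllFeatures(featTab, tk, alpha)))
    write.csv(comparisons, emit("comparisons.csv"), row.names = FALSE)
    grid <- matrix(NA_real_, nrow = length(tasks), ncol = 17,
                   dimnames = list(tasks, .FEATURE_IDS))
    for (i in seq_len(nrow(comparisons)))
      grid[comparisons$task_id[i], comparisons$slot[i]] <-
        comparisons$p_value[i]
    write.csv(data.frame(task_id = rownames(grid), grid,
                         check.names = FALSE),
              emit("feature_pvalues.csv"), row.names = FALSE, na = "")

    stage <- "classify"
    say("[classify] forward-stepwise diagnostic models")
    models <- list(); perfRows <- list(); coefRows <- list()
    for (tk in tasks) {
      td <- taskDiagnostics(featTab, tk, entryP, removalP, threshold)
      models[[tk]] <- td$model
      p <- td$performance
      perfRows[[tk]] <- data.frame(
        task_id = tk, accuracy = p@accuracy, sensitivity = p@sensitivity,
        specificity = p@specificity, auc = p@auc,
        auc_lo = p@aucCI[1], auc_hi = p@aucCI[2],
        n_selected = length(td$model@selected), stringsAsFactors = FALSE)
      if (nrow(td$model@coefTable))
        coefRows[[tk]] <- cbind(task_id = tk, td$model@coefTable)
    }
    performance <- do.call(rbind, perfRows)
    write.csv(performance, emit("task_performance.csv"), row.names = FALSE)
    coefs <- if (length(coefRows)) do.call(rbind, coefRows) else
      data.frame(task_id = character(), term = character())
    write.csv(coefs, emit("model_coefficients.csv"), row.names = FALSE)

    drawTasks <- intersect(tasks, paste0("T", 1:6))
    dragTasks <- intersect(tasks, c("T7", "T8"))
    avgRows <- list()
    if (length(drawTasks))
      avgRows$drawing <- data.frame(
        group = "drawing tasks (average)", t(taskAveragePerformance(
          performance, drawTasks)))
    if (length(dragTasks))
      avgRows$dragging <- data.frame(
        group = "dragging tasks (average)", t(taskAveragePerformance(
          performance, dragTasks)))
    averages <- if (length(avgRows)) do.call(rbind, avgRows) else NULL
    if (!is.null(averages))
      write.csv(averages, emit("task_averages.csv"), row.names = FALSE)

    if (render) {
      stage <- "render"
      say("[render] pseudocolor stroke-order examples")
      for (g in c("HC", "MCI")) {
        sid <- bundle@subjects$subject_id[bundle@subjects$group == g][1]
        s <- Filter(function(x) x@subjectId == sid &&
                      x@taskId == tasks[1], bundle@sessions)[[1]]
        renderPseudocolor(s, path = emit(sprintf(
          "stroke_order_%s_%s.png", g, tasks[1])))
      }
    }
    list(bundle = bundle, featureTable = featTab,
         comparisons = comparisons, models = models,
         performance = performance, averages = averages)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
  say("[done] ", nrow(manifest), " artifacts in ", outDir)
  invisible(c(list(manifest = manifest), res))
}
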