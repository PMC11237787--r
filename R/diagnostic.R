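## Forward-stepwise logistic diagnostic models (likelihood-ratio entry and
## removal, mimicking the classic "Forward: LR" procedure) and their
## in-sample classification performance. Evaluation is in-sample by design
## and therefore optimistic; no cross-validation is attempted.

.asGroupFactor <- function(labels) {
  if (is.factor(labels)) {
    labels <- droplevels(labels)
    if (!all(levels(labels) %in% c("HC", "MCI")))
      stop("labels must be HC/MCI", call. = FALSE)
    factor(labels, levels = c("HC", "MCI"))
  } else if (is.numeric(labels)) {
    factor(ifelse(labels > 0, "MCI", "HC"), levels = c("HC", "MCI"))
  } else {
    factor(as.character(labels), levels = c("HC", "MCI"))
  }
}

#' Fit a logistic regression
#'
#' Maximum likelihood via iteratively reweighted least squares
#' (`stats::glm`), MCI coded 1. Perfect separation is flagged (coefficients
#' are still reported, with a warning); non-convergence is an error.
#'
#' @param x Numeric matrix or `data.frame` of predictors (no missing
#'   values).
#' @param labels Group labels (`HC`/`MCI` factor, or 0/1 with MCI = 1).
#' @return List with `beta` (including intercept), `se`, `logLik`,
#'   `converged`, `separation`, and the `glm` object `fit`.
#' @export
fitLogistic <- function(x, labels) {
  x <- as.data.frame(x)
  y <- .asGroupFactor(labels)
  if (any(is.na(x)))
    stop("missing predictor values; exclude incomplete rows upstream",
         call. = FALSE)
  if (min(table(y)) < 2)
    stop("need at least 2 subjects per class", call. = FALSE)
  dat <- cbind(x, .y = as.integer(y == "MCI"))
  fit <- suppressWarnings(
    glm(.y ~ ., data = dat, family = binomial(),
        control = list(epsilon = 1e-10, maxit = 100)))
  if (!fit$converged)
    stop("logistic fit did not converge after ", fit$iter, " iterations",
         call. = FALSE)
  mu <- fitted(fit)
  separation <- all(mu < 1e-8 | mu > 1 - 1e-8)
  if (separation)
    warning("perfect separation detected; coefficients are unstable")
  sm <- summary(fit)
  list(beta = coef(fit), se = sm$coefficients[, "Std. Error"],
       logLik = as.numeric(logLik(fit)), converged = fit$converged,
       separation = separation, fit = fit)
}

.lrP <- function(fit0, fit1, df = 1) {
  pchisq(fit0$deviance - fit1$deviance, df = df, lower.tail = FALSE)
}

#' Forward-stepwise logistic model selection
#'
#' Repeats: for each unselected candidate, fit the current model plus that
#' candidate and compute the likelihood-ratio p against the current model;
#' enter the candidate with the smallest p if it is below `entryP`
#' (deterministic tie-break by candidate order). After each entry, any
#' selected variable whose likelihood-ratio removal p exceeds `removalP` is
#' removed (largest first). Stops when no entry or removal occurs.
#'
#' @param x Numeric matrix or `data.frame` of candidate predictors.
#' @param labels Group labels (MCI = positive).
#' @param entryP,removalP LR entry / removal thresholds (defaults 0.05 /
#'   0.10).
#' @param taskId Optional task id recorded in the model.
#' @return A [StepwiseModel-class]; its `fit` slot holds the final `glm`
#'   (intercept-only when nothing entered).
#' @export
forwardStepwise <- function(x, labels, entryP = 0.05, removalP = 0.10,
                            taskId = NA_character_) {
  x <- as.data.frame(x)
  if (!ncol(x)) stop("empty candidate set", call. = FALSE)
  y <- .asGroupFactor(labels)
  yi <- as.integer(y == "MCI")
  candidates <- names(x)
  selected <- character()
  log <- character()
  fitFor <- function(vars) {
    dat <- if (length(vars)) cbind(x[vars], .y = yi)
           else data.frame(.y = yi)
    suppressWarnings(glm(.y ~ ., data = dat, family = binomial(),
                         control = list(epsilon = 1e-10, maxit = 100)))
  }
  current <- fitFor(selected)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 50L) { # guard against entry/removal cycling
      log <- c(log, "stopped: iteration cap reached")
      break
    }
    changed <- FALSE
    ## entry step
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      ps <- vapply(pool, function(v) {
        cand <- tryCatch(fitFor(c(selected, v)), error = function(e) NULL)
        if (is.null(cand) || !cand$converged) return(NA_real_)
        .lrP(current, cand)
      }, numeric(1))
      if (any(!is.na(ps)) && min(ps, na.rm = TRUE) < entryP) {
        best <- pool[which.min(ps)] # which.min takes the first: tie-break
        selected <- c(selected, best)
        current <- fitFor(selected)
        log <- c(log, sprintf("enter %s (LR p = %.4g)", best,
                              min(ps, na.rm = TRUE)))
        changed <- TRUE
      }
    }
    ## removal step
    repeat {
      if (!length(selected)) break
      ps <- vapply(selected, function(v) {
        .lrP(fitFor(setdiff(selected, v)), current)
      }, numeric(1))
      if (max(ps) <= removalP) break
      worst <- selected[which.max(ps)]
      selected <- setdiff(selected, worst)
      current <- fitFor(selected)
      log <- c(log, sprintf("remove %s (LR p = %.4g)", worst, max(ps)))
      changed <- TRUE
    }
    if (!changed) break
  }
  cf <- coef(current)
  se <- summary(current)$coefficients[, "Std. Error"]
  terms <- setdiff(names(cf), "(Intercept)")
  z <- qnorm(0.975)
  coefTab <- if (length(terms)) {
    data.frame(term = terms, beta = unname(cf[terms]),
               se = unname(se[terms]),
               or = exp(unname(cf[terms])),
               or_lo = exp(unname(cf[terms] - z * se[terms])),
               or_hi = exp(unname(cf[terms] + z * se[terms])),
               p = 2 * stats::pnorm(-abs(unname(cf[terms] / se[terms]))),
               stringsAsFactors = FALSE)
  } else {
    data.frame(term = character(), beta = numeric(), se = numeric(),
               or = numeric(), or_lo = numeric(), or_hi = numeric(),
               p = numeric(), stringsAsFactors = FALSE)
  }
  new("StepwiseModel", taskId = taskId, selected = selected,
      coefTable = coefTab, intercept = unname(cf["(Intercept)"]),
      entryP = entryP, removalP = removalP,
      fitLog = if (length(log)) log else "no variables entered",
      fit = current)
}

#' Classification performance of predicted probabilities
#'
#' Confusion matrix at the probability threshold (MCI predicted when the
#' probability is at least the threshold; MCI is the positive class),
#' accuracy, sensitivity, specificity, trapezoidal AUC with DeLong 95% CI,
#' and the ROC curve from (0,0) to (1,1).
#'
#' @param probabilities Predicted MCI probabilities in `[0, 1]`.
#' @param labels Group labels.
#' @param threshold Probability threshold (default 0.5).
#' @return A [DiagnosticPerformance-class].
#' @export
classifyMetrics <- function(probabilities, labels, threshold = 0.5) {
  y <- .asGroupFactor(labels)
  if (length(unique(y)) < 2)
    stop("undefined metrics: labels contain a single class", call. = FALSE)
  if (any(probabilities < 0 | probabilities > 1))
    stop("probabilities must be in [0, 1]", call. = FALSE)
  pred <- probabilities >= threshold
  pos <- y == "MCI"
  tp <- sum(pred & pos); fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos); fp <- sum(pred & !pos)
  rocObj <- suppressMessages(
    pROC::roc(response = y, predictor = probabilities,
              levels = c("HC", "MCI"), direction = "<", quiet = TRUE))
  auc <- as.numeric(rocObj$auc)
  aucCI <- tryCatch(
    suppressWarnings( # degenerate at AUC 1: CI collapses to 1-1
      as.numeric(pROC::ci.auc(rocObj, method = "delong"))[c(1, 3)]),
    error = function(e) c(NA_real_, NA_real_))
  ord <- order(1 - rocObj$specificities, rocObj$sensitivities)
  roc <- data.frame(fpr = (1 - rocObj$specificities)[ord],
                    tpr = rocObj$sensitivities[ord])
  new("DiagnosticPerformance",
      accuracy = (tp + tn) / length(y),
      sensitivity = tp / (tp + fn),
      specificity = tn / (tn + fp),
      auc = auc, aucCI = aucCI, roc = roc,
      confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
      threshold = threshold)
}

#' Performance summary from confusion counts
#'
#' The confusion-matrix identities alone: accuracy = (tp+tn)/n, sensitivity
#' = tp/(tp+fn), specificity = tn/(tn+fp). AUC is not defined from counts
#' and is `NA`.
#'
#' @param tp,fn,tn,fp Confusion counts (MCI positive).
#' @return A [DiagnosticPerformance-class] with `auc = NA`.
#' @export
#' @examples
#' performanceFromConfusion(tp = 93, fn = 15, tn = 90, fp = 9)
performanceFromConfusion <- function(tp, fn, tn, fp) {
  new("DiagnosticPerformance",
      accuracy = (tp + tn) / (tp + fn + tn + fp),
      sensitivity = tp / (tp + fn),
      specificity = tn / (tn + fp),
      auc = NA_real_, aucCI = c(NA_real_, NA_real_),
      roc = data.frame(fpr = numeric(), tpr = numeric()),
      confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
      threshold = NA_real_)
}

#' Average sensitivity and specificity across tasks
#'
#' Unweighted arithmetic means over the named tasks, reported to 3
#' decimals (the cross-task summary row).
#'
#' @param perf `data.frame` with columns `task_id` (or `model`),
#'   `sensitivity`, `specificity`.
#' @param taskIds Tasks to average over.
#' @return Named numeric `c(sensitivity=, specificity=)`.
#' @export
taskAveragePerformance <- function(perf, taskIds) {
  idCol <- if ("task_id" %in% names(perf)) "task_id" else "model"
  miss <- setdiff(taskIds, perf[[idCol]])
  if (length(miss))
    stop("unknown task id(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  sel <- perf[[idCol]] %in% taskIds
  c(sensitivity = round(mean(perf$sensitivity[sel]), 3),
    specificity = round(mean(perf$specificity[sel]), 3))
}

#' Fit and evaluate the diagnostic model of one task
#'
#' Builds the task's complete-case feature matrix, runs forward-stepwise
#' selection, and evaluates the selected model in sample.
#'
#' @param featTab Output of [featureTable()].
#' @param task Task id.
#' @param entryP,removalP Stepwise thresholds.
#' @param threshold Classification probability threshold.
#' @return List with `model` ([StepwiseModel-class]) and `performance`
#'   ([DiagnosticPerformance-class]).
#' @export
taskDiagnostics <- function(featTab, task, entryP = 0.05, removalP = 0.10,
                            threshold = 0.5) {
  fm <- taskFeatureMatrix(featTab, task)
  model <- forwardStepwise(fm$x, fm$group, entryP, removalP, taskId = task)
  prob <- as.numeric(predict(model@fit, type = "response"))
  perf <- classifyMetrics(prob, fm$group, threshold)
  list(model = model, performance = perf)
}
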