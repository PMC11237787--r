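## Two-group feature statistics: Lilliefors-corrected Kolmogorov-Smirnov
## normality gate, Welch/pooled t or Mann-Whitney U with Hodges-Lehmann
## shift estimate and distribution-free 95% CI, chi-square for categorical
## tables, Spearman correlation, and the P < alpha significance filter.
## No multiple-testing correction is applied: features are filtered at the
## raw per-test level, mirroring how the feature screen is defined.

#' Lilliefors-corrected normality test
#'
#' One-sample Kolmogorov-Smirnov test against a normal distribution with
#' mean and SD estimated from the sample, using the Lilliefors correction
#' (the plain KS test is anticonservative when parameters are estimated).
#' A constant sample is degenerate and reported as `p = 0` with attribute
#' `degenerate = TRUE`.
#'
#' @param values Numeric vector, `n >= 4`.
#' @return p value.
#' @export
normalityTest <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 4)
    stop("insufficient data: normality test needs n >= 4", call. = FALSE)
  if (stats::sd(values) == 0) {
    p <- 0
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  if (length(values) == 4) return(.lillieMC(values))
  unname(nortest::lillie.test(values)$p.value)
}

## Lilliefors p for n = 4 (below the tabulated range of the closed-form
## approximation) by a fixed-seed Monte-Carlo null; the global RNG state is
## left untouched.
.lillieMC <- function(values, reps = 4000L) {
  ks <- function(x) {
    z <- sort((x - mean(x)) / stats::sd(x))
    fn <- seq_along(z) / length(z)
    max(pmax(abs(fn - stats::pnorm(z)),
             abs(c(0, fn[-length(fn)]) - stats::pnorm(z))))
  }
  obs <- ks(values)
  hasSeed <- exists(".Random.seed", envir = globalenv())
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (hasSeed) assign(".Random.seed", old, envir = globalenv()))
  set.seed(160481219L)
  null <- replicate(reps, ks(rnorm(length(values))))
  mean(null >= obs)
}

.mannWhitneyZ <- function(hc, mci) {
  ## tie-corrected continuity-corrected z for U (MCI vs HC), matching the
  ## p of wilcox.test(correct = TRUE, exact = FALSE)
  n1 <- length(mci); n2 <- length(hc)
  r <- rank(c(mci, hc))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  nties <- table(r)
  sigma <- sqrt((n1 * n2 / 12) *
                ((n1 + n2 + 1) - sum(nties^3 - nties) /
                   ((n1 + n2) * (n1 + n2 - 1))))
  if (sigma == 0) return(0)
  (U - mu - sign(U - mu) * 0.5) / sigma
}

#' Compare a feature between groups
#'
#' The test is chosen by a normality gate: if both groups pass the
#' Lilliefors test at the 0.05 level, a two-tailed t test (Welch by default)
#' is used; otherwise the Mann-Whitney U test (exact when both groups have
#' n <= 12 and no ties, tie-corrected continuity-corrected normal
#' approximation otherwise). The Hodges-Lehmann location-shift estimate
#' (median of all MCI-minus-HC pairwise differences) and its
#' distribution-free 95% CI are always reported.
#'
#' @param hc,mci Numeric samples (each `n >= 4`).
#' @param alpha Significance level for the `significant` flag.
#' @param varEqual Use the pooled-variance t test instead of Welch.
#' @param feature Feature label carried in the result.
#' @param test `"auto"` (the normality gate, default) or an explicit
#'   `"t"` / `"mann_whitney"` override.
#' @return A [GroupComparison-class].
#' @export
#' @examples
#' cmp <- compareFeature(hc = c(1, 2, 3, 4), mci = c(2, 3, 4, 5))
#' cmp@hlEstimate
compareFeature <- function(hc, mci, alpha = 0.05, varEqual = FALSE,
                           feature = "feature",
                           test = c("auto", "t", "mann_whitney")) {
  test <- match.arg(test)
  hc <- hc[!is.na(hc)]; mci <- mci[!is.na(mci)]
  if (!length(hc) || !length(mci))
    stop("empty group in comparison of ", feature, call. = FALSE)
  if (length(hc) < 4 || length(mci) < 4)
    stop("insufficient data: both groups need n >= 4", call. = FALSE)
  normP <- c(HC = normalityTest(hc), MCI = normalityTest(mci))
  bothNormal <- if (test == "auto") all(normP >= 0.05) else test == "t"

  ## HL shift estimate (exact median of all pairwise MCI - HC differences)
  ## with the distribution-free CI, always reported
  hl <- median(as.vector(outer(mci, hc, "-")))
  w <- suppressWarnings(
    wilcox.test(mci, hc, conf.int = TRUE, conf.level = 0.95,
                exact = NULL, correct = TRUE))
  hlCI <- unname(w$conf.int)
  hlCI <- c(min(hlCI[1], hl), max(hlCI[2], hl))

  if (bothNormal) {
    tt <- t.test(mci, hc, var.equal = varEqual)
    testUsed <- "t"; statistic <- unname(tt$statistic); p <- tt$p.value
  } else {
    exactOK <- length(hc) <= 12 && length(mci) <= 12 &&
      !any(duplicated(c(hc, mci)))
    wt <- suppressWarnings(
      wilcox.test(mci, hc, exact = exactOK, correct = TRUE))
    testUsed <- "mann_whitney"
    statistic <- .mannWhitneyZ(hc, mci)
    p <- wt$p.value
  }
  new("GroupComparison", feature = feature,
      nHC = length(hc), nMCI = length(mci), normalityP = normP,
      testUsed = testUsed, statistic = statistic, pValue = p,
      hlEstimate = hl, hlCI = hlCI,
      significant = p < alpha, alpha = alpha)
}

#' Compare all applicable features of one task
#'
#' @param featTab Output of [featureTable()].
#' @param task Task id.
#' @param alpha Significance level.
#' @param varEqual Passed to [compareFeature()].
#' @return `data.frame` with one row per applicable feature slot: `task_id`,
#'   `slot`, `feature`, group sizes, normality p values, `test_used`,
#'   `statistic`, `p_value`, `hl_estimate`, `hl_lo`, `hl_hi`, `significant`.
#' @export
compareAllFeatures <- function(featTab, task, alpha = 0.05,
                               varEqual = FALSE) {
  task <- .checkTaskId(task)
  sel <- featTab$task_id == task
  app <- names(which(.APPLICABILITY[task, ]))
  nm <- featureNames(task)
  rows <- lapply(app, function(slot) {
    v <- featTab[[slot]][sel]
    g <- featTab$group[sel]
    hc <- v[g == "HC"]; mci <- v[g == "MCI"]
    cmp <- tryCatch(
      compareFeature(hc, mci, alpha, varEqual, feature = nm[[slot]]),
      error = function(e) NULL)
    if (is.null(cmp)) return(NULL)
    data.frame(task_id = task, slot = slot, feature = nm[[slot]],
               n_hc = cmp@nHC, n_mci = cmp@nMCI,
               normality_p_hc = cmp@normalityP[["HC"]],
               normality_p_mci = cmp@normalityP[["MCI"]],
               test_used = cmp@testUsed, statistic = cmp@statistic,
               p_value = cmp@pValue, hl_estimate = cmp@hlEstimate,
               hl_lo = cmp@hlCI[1], hl_hi = cmp@hlCI[2],
               significant = cmp@significant,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Filter significant features
#'
#' Returns the feature ids with `p < alpha`, preserving input (slot) order.
#'
#' @param p Named numeric vector of p values (names are feature ids), or a
#'   `data.frame` with columns `slot`/`feature` and `p_value`.
#' @param alpha Significance level.
#' @return Character vector of feature ids; its `length()` is the count the
#'   feature screen reports.
#' @export
#' @examples
#' significantFeatures(c(f1 = 0.03, f2 = 0.5, f3 = 0.001))
significantFeatures <- function(p, alpha = 0.05) {
  if (is.data.frame(p)) {
    ids <- if ("slot" %in% names(p)) p$slot else p$feature
    p <- setNames(p$p_value, ids)
  }
  keep <- !is.na(p) & p < alpha
  names(p)[keep]
}

#' Parse printed p values
#'
#' Converts printed strings such as `".033"`, `"<.001"` or `"0.002"` to
#' numbers; a censored value `"<x"` becomes `x/2` (any value below the
#' printed bound filters identically at conventional levels). Empty cells
#' give `NA`.
#'
#' @param x Character vector.
#' @return Numeric vector.
#' @export
parsePValue <- function(x) {
  nm <- names(x)
  x <- trimws(as.character(x))
  out <- setNames(rep(NA_real_, length(x)), nm)
  cens <- grepl("^<", x)
  out[cens] <- as.numeric(sub("^<", "", x[cens])) / 2
  plain <- !cens & nzchar(x) & x != "-"
  out[plain] <- as.numeric(x[plain])
  out
}

#' Pearson chi-square test for a 2 x k table
#'
#' @param tab Integer matrix (contingency table); all expected counts must
#'   be positive.
#' @return List with `statistic`, `df`, `p`.
#' @export
chiSquareTest <- function(tab) {
  tab <- as.matrix(tab)
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expd == 0))
    stop("zero expected cell count; consider an exact test", call. = FALSE)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Spearman rank correlation
#'
#' Rank correlation with tie handling and a two-sided p via the t
#' approximation.
#'
#' @param x,y Paired numeric vectors, `n >= 5`.
#' @return List with `rho` and `p`.
#' @export
spearmanCor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5)
    stop("insufficient data: Spearman correlation needs n >= 5",
         call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector", call. = FALSE)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
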