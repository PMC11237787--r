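# Logistic fits, forward-stepwise selection, classification metrics.

test_that("single binary predictor recovers the closed-form odds ratio", {
  # 2x2 table tp/fn/tn/fp = 30/10/25/15: OR = (30*25)/(10*15) = 5
  x <- data.frame(exposed = c(rep(1, 30), rep(0, 10), rep(0, 25),
                              rep(1, 15)))
  y <- c(rep("MCI", 40), rep("HC", 40))
  fit <- fitLogistic(x, y)
  expect_equal(unname(exp(fit$beta["exposed"])), 5.0, tolerance = 1e-6)
})

test_that("likelihood is invariant to duplicating every row", {
  set.seed(91)
  x <- data.frame(a = rnorm(40), b = rnorm(40))
  y <- rbinom(40, 1, plogis(x$a))
  f1 <- fitLogistic(x, y)
  f2 <- fitLogistic(rbind(x, x), c(y, y))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-6)
})

test_that("perfect separation is flagged", {
  x <- data.frame(v = c(1:10, 21:30))
  y <- rep(c("HC", "MCI"), each = 10)
  expect_warning(fit <- fitLogistic(x, y), "separation")
  expect_true(fit$separation)
})

test_that("stepwise with entry_p = 0 selects nothing", {
  set.seed(92)
  x <- data.frame(a = rnorm(50), b = rnorm(50))
  y <- rbinom(50, 1, 0.5)
  m <- forwardStepwise(x, y, entryP = 0)
  expect_length(selectedFeatures(m), 0)
  expect_equal(nrow(coefTable(m)), 0)
})

test_that("stepwise finds a strongly predictive feature among noise", {
  set.seed(93)
  hits <- 0L
  for (r in 1:10) {
    n <- 400
    y <- rep(c(0, 1), each = n / 2)
    x <- as.data.frame(matrix(rnorm(n * 9), n, 9))
    names(x) <- paste0("noise", 1:9)
    x$signal <- rnorm(n, mean = y * 1.8) # ~AUC 0.9 predictor
    x <- x[, sample(names(x))] # selection must not depend on position
    m <- forwardStepwise(x, y)
    if (length(selectedFeatures(m)) && selectedFeatures(m)[1] == "signal")
      hits <- hits + 1L
  }
  expect_gte(hits, 9)
})

test_that("stepwise ORs satisfy the exp(beta) identity and CI ordering", {
  set.seed(94)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  x <- data.frame(s1 = rnorm(n, y * 1.2), s2 = rnorm(n, y * 0.8),
                  nn = rnorm(n))
  m <- forwardStepwise(x, y)
  ct <- coefTable(m)
  expect_gt(nrow(ct), 0)
  expect_equal(ct$or, exp(ct$beta), tolerance = 1e-12)
  expect_true(all(ct$or_lo <= ct$or & ct$or <= ct$or_hi))
})

test_that("confusion metrics satisfy their identities", {
  p <- performanceFromConfusion(tp = 95, fn = 13, tn = 82, fp = 17)
  expect_equal(p@sensitivity, 95 / 108)
  expect_equal(p@specificity, 82 / 99)
  expect_equal(p@accuracy, 177 / 207)

  set.seed(95)
  prob <- runif(80)
  y <- rep(c("HC", "MCI"), 40)
  perf <- classifyMetrics(prob, y, threshold = 0.4)
  cf <- perf@confusion
  expect_equal(perf@accuracy, unname((cf["tp"] + cf["tn"]) / sum(cf)))
  expect_equal(perf@sensitivity, unname(cf["tp"] / (cf["tp"] + cf["fn"])))
  expect_equal(perf@specificity, unname(cf["tn"] / (cf["tn"] + cf["fp"])))
})

test_that("AUC equals the concordant-pair oracle and is rank-invariant", {
  set.seed(96)
  for (i in 1:30) {
    nH <- sample(5:20, 1); nM <- sample(5:20, 1)
    prob <- round(runif(nH + nM), 2) # rounding forces ties
    y <- c(rep("HC", nH), rep("MCI", nM))
    perf <- classifyMetrics(prob, y)
    expect_equal(perf@auc, aucOracle(prob[y == "HC"], prob[y == "MCI"]),
                 tolerance = 1e-10)
    # strictly increasing transform leaves AUC unchanged
    perf2 <- classifyMetrics(plogis(3 * prob - 1), y)
    expect_equal(perf2@auc, perf@auc, tolerance = 1e-10)
  }
})

test_that("ROC curves are monotone from (0,0) to (1,1)", {
  set.seed(97)
  prob <- runif(60); y <- rep(c("HC", "MCI"), 30)
  roc <- classifyMetrics(prob, y)@roc
  expect_equal(unlist(roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))

  sep <- classifyMetrics(c(0.1, 0.2, 0.8, 0.9),
                         c("HC", "HC", "MCI", "MCI"))
  expect_equal(sep@auc, 1.0)
  expect_true(any(sep@roc$fpr == 0 & sep@roc$tpr == 1))
})

test_that("single-class labels are an error", {
  expect_error(classifyMetrics(runif(5), rep("MCI", 5)), "single class")
})

test_that("cross-task averages reproduce the published summary row", {
  perf <- publishedTaskPerformance()
  avg <- taskAveragePerformance(perf,
                                perf$model[perf$type == "drawing"])
  expect_equal(unname(avg["sensitivity"]), 0.861)
  expect_equal(unname(avg["specificity"]), 0.838)
  one <- taskAveragePerformance(perf, "sRCFT delayed recall")
  expect_equal(unname(one["sensitivity"]), 0.861)
  expect_equal(unname(one["specificity"]), 0.909)
  expect_error(taskAveragePerformance(perf, "nonexistent task"), "unknown")
})
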