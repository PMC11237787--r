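# Kinematic feature extraction: definitions, attribution, applicability,
# scaling properties.

test_that("thinking time is the first pen-down time", {
  s <- makeSession(list(list(t0 = 1200, dur = 100, comp = "global_1")))
  expect_equal(thinkingTime(s), 1200)
  s0 <- makeSession(list(list(t0 = 0, dur = 100, comp = "global_1")))
  expect_equal(thinkingTime(s0), 0)
})

test_that("paint time sums stroke durations of the class", {
  s <- makeSession(list(list(t0 = 0, dur = 300, comp = "number"),
                        list(t0 = 500, dur = 200, comp = "number"),
                        list(t0 = 900, dur = 150, comp = "circle")),
                   task = "T1")
  expect_equal(componentPaintTime(s, "number"), 500)
  expect_equal(componentPaintTime(s, "circle"), 150)
  pt <- componentPaintTime(s, "pointer")
  expect_equal(as.numeric(pt), 0)
  expect_true(isTRUE(attr(pt, "no_ink")))
  expect_error(componentPaintTime(s, "global_1"), "applicability")
})

test_that("in-air gaps are charged to the upcoming stroke's component", {
  s <- makeSession(list(list(t0 = 0, dur = 100, comp = "circle"),
                        list(t0 = 400, dur = 100, comp = "number")),
                   task = "T1")
  expect_equal(componentUnpaintedTime(s, "number"), 300)
  expect_equal(componentUnpaintedTime(s, "circle"), 0)
  one <- makeSession(list(list(t0 = 700, dur = 100, comp = "circle")),
                     task = "T1")
  expect_equal(componentUnpaintedTime(one, taskComponents("T1")), 0)
})

test_that("class paint times partition total on-surface time", {
  set.seed(61)
  for (i in 1:20) {
    s <- randomSession("T1", nStrokes = sample(3:12, 1))
    total <- sum(vapply(taskComponents("T1"), function(cl)
      componentPaintTime(s, cl), numeric(1)))
    expect_equal(total, sum(strokeDurations(s)))
  }
})

test_that("stroke counts and internal lifts match a brute-force pair scan", {
  s <- makeSession(list(list(t0 = 0, dur = 50, comp = "circle"),
                        list(t0 = 100, dur = 50, comp = "circle"),
                        list(t0 = 200, dur = 50, comp = "circle")),
                   task = "T1")
  expect_equal(componentStrokeCounts(s, "circle"),
               c(total = 3, penup = 2))
  one <- makeSession(list(list(t0 = 0, dur = 50, comp = "number")),
                     task = "T1")
  expect_equal(componentStrokeCounts(one, "number"),
               c(total = 1, penup = 0))

  set.seed(62)
  for (i in 1:30) {
    s <- randomSession("T6", nStrokes = sample(2:15, 1))
    comps <- strokeTable(s)$component
    for (cl in unique(comps)) {
      oracle <- sum(comps[-1] == comps[-length(comps)] &
                      comps[-1] == cl)
      cnt <- componentStrokeCounts(s, cl)
      expect_equal(unname(cnt["penup"]), oracle)
      expect_equal(unname(cnt["total"]), sum(comps == cl))
      expect_lte(cnt["penup"], cnt["total"])
    }
  }
})

test_that("painting frequency is strokes per on-surface second", {
  s <- makeSession(list(list(t0 = 0, dur = 500, comp = "circle"),
                        list(t0 = 600, dur = 500, comp = "circle"),
                        list(t0 = 1200, dur = 500, comp = "circle"),
                        list(t0 = 1800, dur = 500, comp = "circle")),
                   task = "T1")
  expect_equal(paintingFrequency(s, "circle"), 2.0)
  one <- makeSession(list(list(t0 = 0, dur = 500, comp = "number")),
                     task = "T1")
  expect_equal(paintingFrequency(one, "number"), 2.0)
})

test_that("time scaling scales time features and divides frequencies", {
  set.seed(63)
  s <- randomSession("T1", nStrokes = 8)
  ev2 <- penEvents(s); ev2$t <- ev2$t * 2L
  s2 <- drawingSession("rs", "T1", ev2, strokeTable(s), strict = FALSE)
  for (cl in taskComponents("T1")) {
    expect_equal(componentPaintTime(s2, cl),
                 2 * componentPaintTime(s, cl))
    expect_equal(componentUnpaintedTime(s2, cl),
                 2 * componentUnpaintedTime(s, cl))
    if (componentPaintTime(s, cl) > 0)
      expect_equal(paintingFrequency(s2, cl),
                   paintingFrequency(s, cl) / 2)
  }
  expect_equal(thinkingTime(s2), 2 * thinkingTime(s))

  # translation changes thinking time only
  ev3 <- penEvents(s); ev3$t <- ev3$t + 1000L
  s3 <- drawingSession("rs", "T1", ev3, strokeTable(s), strict = FALSE)
  expect_equal(thinkingTime(s3), thinkingTime(s) + 1000)
  for (cl in taskComponents("T1"))
    expect_equal(componentPaintTime(s3, cl), componentPaintTime(s, cl))
})

test_that("feature vectors honor the per-task applicability matrix", {
  cfg <- effectConfig("default", nPerGroup = c(HC = 2, MCI = 2), seed = 8)
  cb <- generateCohort(cfg)
  expected <- list(
    T1 = 1:17,
    T5 = c(1, 3, 6, 9, 12, 15, 17),
    T7 = c(1, 2, 4, 14, 17),
    T8 = c(1, 5, 7, 16, 17))
  for (s in cohortSessions(cb)) {
    fv <- extractFeatures(s, scoreSession(s))
    vals <- featureValues(fv)
    app <- featureApplicability(taskId(s))
    expect_true(all(is.na(vals[!app])))
    expect_true(all(!is.na(vals[app])))
    tid <- taskId(s)
    if (tid %in% names(expected))
      expect_equal(which(app), expected[[tid]], ignore_attr = TRUE)
  }
})

test_that("the T7 drag frequency covers both dragged element types", {
  s <- makeSession(list(list(t0 = 0, dur = 1000, comp = "number"),
                        list(t0 = 1100, dur = 500, comp = "number"),
                        list(t0 = 1700, dur = 500, comp = "pointer")),
                   task = "T7", source = "drag")
  fv <- featureValues(extractFeatures(s))
  expect_equal(unname(fv["f02"]), 1500) # number drag time
  expect_equal(unname(fv["f04"]), 500)  # pointer drag time
  expect_equal(unname(fv["f14"]), 3 / 2) # 3 drags in 2 s on-surface
})

test_that("featureExperiment wraps the task matrix with covariates", {
  cfg <- effectConfig("default", nPerGroup = c(HC = 3, MCI = 3), seed = 4)
  cb <- generateCohort(cfg, tasks = "T5")
  ft <- featureTable(cb)
  se <- featureExperiment(ft, cohortSubjects(cb), "T5")
  expect_s4_class(se, "SummarizedExperiment")
  expect_equal(dim(se), c(17, 6))
  expect_equal(sum(SummarizedExperiment::rowData(se)$applicable), 7)
  expect_identical(SummarizedExperiment::colData(se)$group,
                   cohortSubjects(cb)$group)
})
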