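## Synthetic cohort generator. Emulates the statistical structure the
## analysis assumes: two groups (HC, MCI) with MCI showing longer in-air
## times, longer painting/drag times, more internal pen lifts, and lower
## rubric scores, at configurable effect sizes. Timing draws are log-normal
## (positive, right-skewed — matching the nonnormal features the two-group
## tests must handle); rubric scores are generated through the annotation
## layer so the scorers themselves are exercised.

.DEFAULT_HC <- list(
  think_median = 1500, think_sigma = 0.5,
  stroke_median = 600, stroke_sigma = 0.5,
  air_median = 400, air_sigma = 0.6,
  strokes_per_component = 2, internal_lift_prob = 0.15,
  quality = 0.92)

.DEFAULT_MCI <- list(
  think_median = 2000, think_sigma = 0.5,
  stroke_median = 900, stroke_sigma = 0.5,
  air_median = 800, air_sigma = 0.6,
  strokes_per_component = 2, internal_lift_prob = 0.35,
  quality = NA) # derived from scoreShift unless overridden

## Per-session tempo: subjects differ in overall psychomotor speed; one
## log-normal factor per session multiplies all three timing medians, which
## also induces the within-task correlation between time features seen in
## real pen data.
.TEMPO_SIGMA <- 0.25

#' Build a synthetic-cohort effect configuration
#'
#' Presets encode the study conditions:
#' \describe{
#'   \item{default}{HC/MCI contrasts as reported qualitatively — MCI in-air
#'     (unpainted) median doubled (400 -> 800 ms), stroke/drag durations 1.5x
#'     (600 -> 900 ms), thinking time 1500 -> 2000 ms, internal lift
#'     probability 0.15 -> 0.35, rubric score shift -2 points (0-18 scale);
#'     cohort split 99 HC / 108 MCI.}
#'   \item{strong}{Same contrasts with 100 subjects per group (the
#'     recovery-experiment condition).}
#'   \item{null}{Both groups share the HC distributions, score shift 0,
#'     50 per group (the calibration condition).}
#' }
#' Any field can be overridden via `hc`/`mci`/`scoreShift`/`nPerGroup`.
#'
#' @param preset `"default"`, `"strong"` or `"null"`.
#' @param hc,mci Named lists overriding per-group parameters
#'   (`think_median`, `think_sigma`, `stroke_median`, `stroke_sigma`,
#'   `air_median`, `air_sigma`, `strokes_per_component`,
#'   `internal_lift_prob`, `quality`).
#' @param scoreShift Additive shift (points, 0-18 figure scale) on the MCI
#'   expected rubric score; drives the MCI drawing-quality propensity
#'   `quality_MCI = quality_HC + scoreShift/18` unless `mci$quality` is
#'   given.
#' @param nPerGroup Named integer vector `c(HC=, MCI=)`.
#' @param seed Integer base seed.
#' @return An [EffectConfig-class].
#' @export
#' @examples
#' effectConfig("strong")
effectConfig <- function(preset = c("default", "strong", "null"),
                         hc = list(), mci = list(), scoreShift = NULL,
                         nPerGroup = NULL, seed = NULL) {
  preset <- match.arg(preset)
  hcPar <- utils::modifyList(.DEFAULT_HC, hc)
  mciBase <- switch(preset,
    default = .DEFAULT_MCI,
    strong = .DEFAULT_MCI,
    null = .DEFAULT_HC)
  mciPar <- utils::modifyList(mciBase, mci)
  if (is.null(scoreShift)) scoreShift <- if (preset == "null") 0 else -2
  if (is.na(mciPar$quality))
    mciPar$quality <- min(1, max(0, hcPar$quality + scoreShift / 18))
  if (is.null(nPerGroup)) {
    nPerGroup <- switch(preset,
      default = c(HC = 99L, MCI = 108L),
      strong = c(HC = 100L, MCI = 100L),
      null = c(HC = 50L, MCI = 50L))
  }
  if (is.null(seed)) seed <- 20260930L
  cfg <- new("EffectConfig", hc = hcPar, mci = mciPar,
             scoreShift = as.numeric(scoreShift),
             nPerGroup = setNames(as.integer(nPerGroup),
                                  names(nPerGroup)),
             seed = as.integer(seed))
  validObject(cfg)
  cfg
}

.rlnormMed <- function(n, median, sigma) rlnorm(n, log(median), sigma)

.demo <- function(group) {
  ## Marginals near the published cohort characteristics (age 71.34 (4.48)
  ## MCI / 70.11 (4.00) HC, etc.)
  if (group == "MCI") {
    list(age = c(71.34, 4.48), woman = 0.592, left = 0.102,
         edu = c(6.21, 3.28), sleep = c(5.93, 1.20), exercise = 0.481,
         device = c(5.52, 2.54), moca = c(24.09, 1.13), mmse = c(25.31, 1.13))
  } else {
    list(age = c(70.11, 4.00), woman = 0.576, left = 0.071,
         edu = c(6.81, 2.89), sleep = c(6.28, 1.06), exercise = 0.515,
         device = c(5.87, 2.52), moca = c(27.04, 1.21), mmse = c(28.00, 0.92))
  }
}

#' Generate one synthetic subject
#'
#' Demographics are drawn near the published cohort marginals; eligibility
#' is enforced exactly: MCI subjects get MoCA < 26 and CDR 0.5, HC subjects
#' MoCA >= 26 and CDR 0. Uses the current RNG state.
#'
#' @param group `"HC"` or `"MCI"`.
#' @param subjectId Identifier for the subject.
#' @return One-row subject `data.frame`.
#' @export
generateSubject <- function(group = c("HC", "MCI"), subjectId = "S001") {
  group <- match.arg(group)
  d <- .demo(group)
  clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  moca <- if (group == "MCI")
    clip(round(rnorm(1, d$moca[1], d$moca[2])), 18, 25)
  else
    clip(round(rnorm(1, d$moca[1], d$moca[2])), 26, 30)
  mmse <- if (group == "MCI")
    clip(round(rnorm(1, d$mmse[1], d$mmse[2])), 20, 30)
  else
    clip(round(rnorm(1, d$mmse[1], d$mmse[2])), 24, 30)
  data.frame(
    subject_id = subjectId,
    group = group,
    age = round(clip(rnorm(1, d$age[1], d$age[2]), 65, 95), 1),
    gender = if (runif(1) < d$woman) "woman" else "man",
    hand_preference = if (runif(1) < d$left) "left" else "right",
    education_years = round(clip(rnorm(1, d$edu[1], d$edu[2]), 0, 22), 1),
    sleep_hours = round(clip(rnorm(1, d$sleep[1], d$sleep[2]), 3, 12), 1),
    exercise_habit = if (runif(1) < d$exercise) "yes" else "no",
    device_years = round(clip(rnorm(1, d$device[1], d$device[2]), 0, 20), 1),
    moca = moca,
    mmse = mmse,
    cdr = if (group == "MCI") 0.5 else 0,
    stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## Schematic geometry. Stroke paths are schematic polylines per component
## template on the 2160 x 1620 device canvas; geometric realism is
## irrelevant to the time/count features.
## ---------------------------------------------------------------------------

.clockPos <- function(k, r = 450, cx = 1080, cy = 810) {
  a <- pi / 2 - k * pi / 6
  c(cx + r * cos(a), cy - r * sin(a))
}

.componentTemplate <- function(task, component) {
  fam <- .taskFamily(task)
  if (fam %in% c("clockDraw")) {
    switch(component,
      circle = {
        a <- seq(pi / 2, pi / 2 + 2 * pi, length.out = 17)
        cbind(1080 + 600 * cos(a), 810 - 600 * sin(a))
      },
      number = do.call(rbind, lapply(1:12, function(k) {
        p <- .clockPos(k)
        rbind(p + c(-25, -25), p + c(25, 25))
      })),
      pointer = rbind(.clockPos(11, 250), c(1080, 810), .clockPos(2, 350)))
  } else if (fam %in% c("figureDraw", "pointLine")) {
    ## 5 global components frame the figure, 4 local details sit inside.
    switch(component,
      global_1 = rbind(c(480, 360), c(1680, 360), c(1680, 1260),
                       c(480, 1260), c(480, 360)),
      global_2 = rbind(c(480, 810), c(1680, 810)),
      global_3 = rbind(c(480, 360), c(1680, 1260)),
      global_4 = rbind(c(1080, 360), c(1080, 1260)),
      global_5 = rbind(c(1680, 360), c(1920, 810), c(1680, 1260)),
      local_1 = rbind(c(600, 480), c(720, 540), c(600, 600)),
      local_2 = rbind(c(1440, 480), c(1560, 480), c(1560, 600)),
      local_3 = rbind(c(600, 1020), c(720, 1140), c(840, 1020)),
      local_4 = rbind(c(1380, 1020), c(1500, 1140), c(1380, 1140)))
  } else { # clockDrag: path from the drag area (bottom) to the target
    NULL
  }
}

.interpPath <- function(pts, frac) {
  ## points at arc-length fractions frac of polyline pts (vectorized)
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  s <- frac * cum[length(cum)]
  i <- pmin(findInterval(s, cum, rightmost.closed = TRUE), nrow(pts) - 1)
  w <- (s - cum[i]) / pmax(seg[i], 1e-9)
  pts[i, , drop = FALSE] + w * (pts[i + 1, , drop = FALSE] -
                                  pts[i, , drop = FALSE])
}

.splitPath <- function(pts, n, pointsPerStroke = 4L) {
  fr <- unlist(lapply(seq_len(n), function(j)
    seq((j - 1) / n, j / n, length.out = pointsPerStroke)))
  all <- .interpPath(pts, fr)
  lapply(seq_len(n), function(j)
    all[((j - 1) * pointsPerStroke + 1):(j * pointsPerStroke), ,
        drop = FALSE])
}

## ---------------------------------------------------------------------------
## Annotation generation (quality propensity q in [0,1])
## ---------------------------------------------------------------------------

.genAnnotation <- function(task, q) {
  fam <- .taskFamily(task)
  bern <- function(p, n = 1) runif(n) < min(1, max(0, p))
  if (fam %in% c("figureDraw", "pointLine")) {
    list(components = data.frame(
      component = .FIGURE_COMPONENTS,
      accurately_drawn = bern(q, 9),
      correctly_located = bern(q, 9),
      identifiable = bern(0.8, 9)))
  } else if (fam == "clockDraw") {
    list(contour_acceptable = bern(min(1, q + 0.05)),
         numbers = data.frame(
           digit = 1:12,
           present = bern(min(1, q + 0.06), 12),
           in_order = bern(min(1, q + 0.05), 12),
           position_ok = bern(q, 12)),
         hands_indicate_11_10 = {
           u <- runif(1)
           if (u < q) "correct"
           else if (u < q + 0.6 * (1 - q)) "minor_error"
           else "major_error"
         },
         clock_recognizable = bern(1 - 0.5 * (1 - q)^2))
  } else {
    list(numbers_position_ok = bern(min(1, q + 0.03)),
         numbers_order_ok = bern(min(1, q + 0.04)),
         pointers_ok = bern(min(1, q + 0.02)))
  }
}

## ---------------------------------------------------------------------------
## Session generation
## ---------------------------------------------------------------------------

.componentRuns <- function(task, par) {
  fam <- .taskFamily(task)
  if (fam == "clockDrag") {
    ## each number (12) and each pointer (2) is one drag segment
    comps <- c(rep("number", 12), rep("pointer", 2))
    lapply(seq_along(comps), function(i) {
      k <- if (i <= 12) i else c(11, 2)[i - 12]
      target <- if (i <= 12) .clockPos(i) else .clockPos(k, 300)
      from <- c(200 + (i %% 12) * 150, 1500)
      list(component = comps[i],
           paths = list(rbind(from, (from + target) / 2, target)))
    })
  } else {
    comps <- if (fam == "clockDraw") .CLOCK_COMPONENTS else .FIGURE_COMPONENTS
    lapply(comps, function(cl) {
      ## potential sub-strokes K ~ 1 + Poisson(spc - 1); each of the K - 1
      ## boundaries becomes an actual pen lift with prob internal_lift_prob,
      ## so internal_lift_prob = 0 forces a single stroke per component.
      K <- 1L + rpois(1, max(0, par$strokes_per_component - 1))
      splits <- if (K > 1L) rbinom(1, K - 1L, par$internal_lift_prob) else 0L
      n <- 1L + splits
      list(component = cl,
           paths = .splitPath(.componentTemplate(task, cl), n))
    })
  }
}

#' Generate one synthetic session
#'
#' Emits a legal event stream for the subject's group: a log-normal thinking
#' time before the first down, one contiguous run of strokes per component
#' (every component of the task appears), log-normal stroke durations and
#' in-air gaps, and an annotation consistent with the group's
#' drawing-quality propensity. Uses the current RNG state.
#'
#' @param subject One-row subject `data.frame` (from [generateSubject()]).
#' @param task Task id `"T1"`..`"T8"`.
#' @param config An [EffectConfig-class].
#' @return A [DrawingSession-class] that passes [validateSession()].
#' @export
generateSession <- function(subject, task, config) {
  task <- .checkTaskId(task)
  par <- if (subject$group == "MCI") config@mci else config@hc
  tempo <- rlnorm(1, 0, .TEMPO_SIGMA)
  src <- if (.taskFamily(task) == "clockDrag") "drag" else "stylus"

  runs <- .componentRuns(task, par)
  strokes <- list(); comps <- character()
  for (r in runs) {
    for (p in r$paths) {
      strokes[[length(strokes) + 1L]] <- p
      comps <- c(comps, r$component)
    }
  }
  nS <- length(strokes)
  durs <- pmax(1, round(.rlnormMed(nS, par$stroke_median * tempo,
                                   par$stroke_sigma)))
  gaps <- pmax(1, round(.rlnormMed(nS, par$air_median * tempo,
                                   par$air_sigma)))
  gaps[1] <- pmax(0, round(.rlnormMed(1, par$think_median * tempo,
                                      par$think_sigma)))
  nPts <- vapply(strokes, nrow, integer(1))
  ends <- cumsum(nPts)
  starts <- ends - nPts + 1L
  downT <- cumsum(gaps + c(0, durs[-nS])) # down time of each stroke
  tAll <- integer(sum(nPts)); xAll <- integer(sum(nPts))
  yAll <- integer(sum(nPts)); phAll <- character(sum(nPts))
  for (i in seq_len(nS)) {
    pts <- round(strokes[[i]])
    m <- nPts[i]
    idx <- starts[i]:ends[i]
    tAll[idx] <- cummax(downT[i] + as.integer(round(
      seq(0, durs[i], length.out = m))))
    xAll[idx] <- as.integer(pts[, 1])
    yAll[idx] <- as.integer(pts[, 2])
    phAll[idx] <- c("down", rep("move", m - 2L), "up")
  }
  events <- data.frame(t = as.integer(tAll), x = xAll, y = yAll,
                       phase = phAll, source = src,
                       stringsAsFactors = FALSE)
  strokeTab <- data.frame(component = comps, start = starts, end = ends,
                          stringsAsFactors = FALSE)
  ann <- .genAnnotation(task, par$quality)
  new("DrawingSession", subjectId = subject$subject_id,
      taskId = unname(task),
      events = events, strokes = strokeTab, annotation = ann,
      sessionEndMs = as.integer(max(tAll)))
}

#' Generate a full synthetic cohort
#'
#' Subjects and one session per task per subject, reproducible from the
#' config seed. Each subject uses an RNG substream derived from
#' `(seed, subject counter)`, so cohorts are reproducible independent of
#' generation order.
#'
#' @param config An [EffectConfig-class] (see [effectConfig()]).
#' @param tasks Task ids to generate (default all 8).
#' @param sessionsPath,cohortPath Optional output paths; when given, the
#'   session JSON-Lines file and cohort CSV are written.
#' @return A [CohortBundle-class].
#' @export
#' @examples
#' cb <- generateCohort(effectConfig("null", nPerGroup = c(HC = 3, MCI = 3)))
#' cb
generateCohort <- function(config = effectConfig(), tasks = taskIds(),
                           sessionsPath = NULL, cohortPath = NULL) {
  validObject(config)
  tasks <- unname(vapply(tasks, .checkTaskId, character(1)))
  groups <- rep(c("HC", "MCI"), config@nPerGroup[c("HC", "MCI")])
  n <- length(groups)
  ids <- sprintf("S%04d", seq_len(n))
  subjects <- vector("list", n)
  sessions <- vector("list", n * length(tasks))
  for (i in seq_len(n)) {
    set.seed((as.numeric(config@seed) * 1009 + i * 7919) %% 2147483647)
    subjects[[i]] <- generateSubject(groups[i], ids[i])
    for (j in seq_along(tasks)) {
      sessions[[(i - 1L) * length(tasks) + j]] <-
        generateSession(subjects[[i]], tasks[j], config)
    }
  }
  bundle <- new("CohortBundle",
                subjects = do.call(rbind, subjects),
                sessions = sessions, config = config)
  if (!is.null(sessionsPath)) writeSessions(bundle@sessions, sessionsPath)
  if (!is.null(cohortPath)) writeCohort(bundle@subjects, cohortPath)
  bundle
}
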