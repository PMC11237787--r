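# Fixtures built in code: tiny hand-constructed sessions and random legal
# event streams for property tests.

# events from a compact spec: list of strokes, each list(t0, dur, comp, nmove)
makeEvents <- function(strokes, source = "stylus") {
  rows <- lapply(strokes, function(s) {
    nm <- if (is.null(s$nmove)) 1L else s$nmove
    tt <- round(seq(s$t0, s$t0 + s$dur, length.out = nm + 2L))
    data.frame(t = as.integer(tt), x = seq_len(nm + 2L) * 10L,
               y = seq_len(nm + 2L) * 10L,
               phase = c("down", rep("move", nm), "up"),
               source = source, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

makeSession <- function(strokes, task = "T5", subject = "s1",
                        source = "stylus", annotation = list(),
                        sessionEnd = NULL) {
  ev <- makeEvents(strokes, source)
  seg <- segmentStrokes(ev)
  st <- data.frame(component = vapply(strokes, function(s) s$comp,
                                      character(1)),
                   start = seg$start, end = seg$end)
  drawingSession(subject, task, ev, st, annotation, sessionEnd,
                 strict = FALSE)
}

# random legal alternating event stream (down [moves] up, optional air moves)
randomEventStream <- function(nStrokes, maxGap = 500L) {
  t <- 0L
  rows <- list()
  for (i in seq_len(nStrokes)) {
    t <- t + sample.int(maxGap, 1)
    nm <- sample(0:3, 1)
    dur <- sample.int(800L, 1)
    tt <- as.integer(round(seq(t, t + dur, length.out = nm + 2L)))
    rows[[length(rows) + 1L]] <- data.frame(
      t = tt, x = sample.int(2160, nm + 2L, replace = TRUE),
      y = sample.int(1620, nm + 2L, replace = TRUE),
      phase = c("down", rep("move", nm), "up"), source = "stylus",
      stringsAsFactors = FALSE)
    t <- t + dur
    if (i < nStrokes && runif(1) < 0.3) { # in-air travel
      t2 <- t + sample.int(50L, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        t = t2, x = 1L, y = 1L, phase = "move", source = "stylus",
        stringsAsFactors = FALSE)
      t <- t2
    }
  }
  do.call(rbind, rows)
}

# random labelled session on task's components
randomSession <- function(task = "T5", nStrokes = 8L) {
  ev <- randomEventStream(nStrokes)
  seg <- segmentStrokes(ev)
  comps <- sample(taskComponents(task), nrow(seg), replace = TRUE)
  st <- data.frame(component = comps, start = seg$start, end = seg$end)
  drawingSession("rs", task, ev, st, list(), strict = FALSE)
}

perfectFigureAnnotation <- function() {
  data.frame(component = c(paste0("global_", 1:5), paste0("local_", 1:4)),
             accurately_drawn = TRUE, correctly_located = TRUE,
             identifiable = TRUE)
}

perfectClockAnnotation <- function() {
  list(contour_acceptable = TRUE,
       numbers = data.frame(digit = 1:12, present = TRUE, in_order = TRUE,
                            position_ok = TRUE),
       hands_indicate_11_10 = "correct",
       clock_recognizable = TRUE)
}

randomClockAnnotation <- function() {
  ann <- perfectClockAnnotation()
  ann$contour_acceptable <- runif(1) < 0.8
  ann$numbers$present <- runif(12) < 0.9
  ann$numbers$in_order <- runif(12) < 0.9
  ann$numbers$position_ok <- runif(12) < 0.8
  ann$hands_indicate_11_10 <- sample(c("correct", "minor_error",
                                       "major_error"), 1)
  ann$clock_recognizable <- runif(1) < 0.9
  ann
}

# brute-force oracles
hlOracle <- function(a, b) median(as.vector(outer(b, a, "-")))

aucOracle <- function(scoreHC, scoreMCI) {
  cmp <- outer(scoreMCI, scoreHC, function(m, h)
    (m > h) + 0.5 * (m == h))
  mean(cmp)
}
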