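---
title: "Hand-motor-function analysis of tablet drawing and dragging tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hand-motor-function analysis of tablet drawing and dragging tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inkcog)
```

## The screening problem

Mild cognitive impairment (MCI) is the intermediate stage between normal
age-related decline and dementia. Drawing tasks administered on a pen
tablet expose *how* a figure is produced, not just the finished figure:
timestamped pen events reveal hesitations in the air between strokes,
slowed on-surface movement, fragmented strokes, and degraded figure
quality. `inkcog` implements a complete analysis pipeline for such data
across eight tasks:

| Task | Description | Rubric |
|------|-------------|--------|
| T1 | digital Clock Drawing Test (dCDT), single task | Schulman 1–6 |
| T2–T4 | dCDT under a concurrent verbal load (counting backward, animal naming, serial-3 subtraction) | Schulman 1–6 |
| T5 | simplified Rey–Osterrieth Complex Figure (sRCFT), raw copy | 0–18 |
| T6 | sRCFT, 10-minute delayed recall | 0–18 |
| T7 | clock drag-and-drop (numbers and hands dragged into a given face) | 0–3 |
| T8 | sRCFT point-and-line (dot-connection reproduction) | 0–18 |

Each session is an ordered stream of `down`/`move`/`up` events with
millisecond timestamps and pixel coordinates (2160×1620 tablet canvas,
top-left origin). A stroke is a maximal down..up run; strokes carry a
component label (clock tasks: `circle`, `number`, `pointer`; figure
tasks: 5 global and 4 local components; the drag task: `number`,
`pointer`). Labels are supplied by the generator or an annotator — the
package deliberately does not attempt geometric component recognition.

## The 17 features

For each session the package computes up to 17 features, following a
fixed applicability matrix (`featureApplicability()`); slots a task does
not define are *missing*, never zero, and are excluded from downstream
statistics rather than imputed.

Timing definitions, chosen once and applied everywhere:

* **Thinking time** (slot 1): time from session start to the first
  pen-down.
* **Painting / drag time** (slots 2–4, and the figure sums in 3, 5, 7):
  sum of on-surface stroke durations of a component class. For the
  point-and-line task, the "global drawing time" and "local drawing
  time" slots are the paint-time sums over the global respectively local
  components.
* **Unpainted time** (slots 5–7): each in-air gap (down of stroke *i*
  minus up of stroke *i−1*) is charged to the *upcoming* stroke's
  component. Rationale: the in-air interval reflects planning for the
  element about to be drawn — the hand "switching from one stroke to the
  next". The gap before the very first stroke is thinking time, not
  unpainted time. These conventions give an exact identity used as a
  test oracle:

  $$\text{thinking} + \sum_c \text{paint}_c + \sum_c \text{unpainted}_c
    = t(\text{last pen-up})$$

* **Stroke counts** (slots 8–10) and **pen-up strokes** (slots 11–13):
  the pen-up (internal lift) count is the number of in-air transitions
  whose flanking strokes carry the *same* component label — lifts inside
  one element's drawing run, the only lift-derived integer distinct from
  the total stroke count. For composite classes (the whole figure) the
  definition is applied label-wise.
* **Painting frequency** (slots 14–16): strokes per second of
  *on-surface* time. The alternative (per total elapsed time) was
  rejected because it would conflate the frequency slots with the
  unpainted-time slots.
* **Score** (slot 17): the task rubric total.

## Rubrics

* **sRCFT (0–18)**: each of 9 equally weighted components scores 2
  (accurately drawn ∧ correctly located), 1 (exactly one of the two),
  0.5 (neither, but identifiable), else 0. Identifiability is only
  consulted when accuracy and location both fail. The point-and-line
  task uses the same rule unchanged.
* **Schulman (1–6)**: the published criteria are cited rather than
  reprinted in the source material, so the tier ladder is fixed here and
  isolated in one documented table (`.SCHULMAN_LADDER` in
  `R/scoring.R`): 6 = unrecognizable clock; 5 = more than 6 number
  faults (a fault is a missing or misplaced digit); 4 = any out-of-order
  digit or more than 2 number faults; 3 = major hand error with intact
  layout; 2 = one or two number faults, a minor hand error, or an
  unacceptable contour; 1 = perfect. The ladder is antitone in fault
  count within tiers, a property the tests sample.
* **Drag clock (0–3)**: one point each for numbers position, numbers
  order, and pointer indication.

Scoring consumes structured annotations, not raw ink: the reference
scores for such tasks are assigned with clinician-interpretable rules,
and automatic geometric scoring is a different (unsolved) problem. The
synthetic generator emits annotations; a human annotator could supply
them for real sessions.

## The synthetic cohort generator

There is no public corpus of labelled MCI pen-stroke sessions, so the
package ships a generator (`effectConfig()`, `generateCohort()`) whose
defaults *are* the study conditions the analysis assumes:

* **Timing**: log-normal distributions for thinking time, stroke
  duration and in-air gaps — times are positive and right-skewed, which
  is also why the analysis pipeline needs a nonparametric branch.
  Defaults (HC): thinking median 1500 ms (σ = 0.5), stroke 600 ms
  (σ = 0.5), in-air 400 ms (σ = 0.6). MCI contrasts: in-air median ×2,
  stroke duration ×1.5, thinking 2000 ms — encoding longer switch times,
  slower drawing and slower dragging for the MCI group.
* **Tempo heterogeneity**: one log-normal factor (σ = 0.25) per session
  multiplies all three medians, modelling between-subject psychomotor
  speed differences; it induces the realistic positive correlation
  between time features within a task.
* **Strokes and lifts**: each component is drawn as one contiguous run.
  A run has `1 + Poisson(strokes_per_component − 1)` *potential*
  sub-strokes and each internal boundary becomes an actual pen lift with
  probability `internal_lift_prob` (0.15 HC vs 0.35 MCI). Consequently
  `internal_lift_prob = 0` forces single-stroke runs and zero pen-up
  counts, while the pen-up feature remains exactly the equal-label
  adjacent-pair count. Drag-task sessions instead contain one drag
  segment per dragged element (12 numbers, 2 hands).
* **Scores through annotations**: a drawing-quality propensity `q`
  (0.92 HC) drives every annotation flag; the MCI propensity is
  `q + scoreShift/18` with a default shift of −2 points on the 0–18
  scale, so MCI scores are lower (and Schulman ratings higher) because
  the *annotations* are worse — the scorers themselves are exercised.
* **Demographics**: drawn near the published cohort marginals (MCI age
  71.34 (4.48), MoCA 24.09 (1.13), etc.), with eligibility enforced
  exactly: MCI ⇒ MoCA < 26 and CDR 0.5. The default cohort split is
  99 HC / 108 MCI; the `strong` preset uses 100/100 and the `null`
  preset removes every contrast at 50/50.
* **Geometry is schematic**: polylines per component template. The 17
  features are time- and count-based, so trajectory realism is
  deliberately out of scope; the generator does **not** emulate
  handwriting shape, pressure/tilt, device jitter, or content of the
  concurrent verbal task. Passing tests therefore validate the
  *statistical machinery*, not shape-sensitive claims about real ink.
* **Reproducibility**: each subject uses an RNG substream derived from
  `(seed, subject counter)`, so a cohort is bit-reproducible and
  independent of generation order.

## Statistics

Per feature and task, `compareFeature()` reproduces the canonical
two-stage recipe: a Lilliefors-corrected Kolmogorov–Smirnov test per
group (plain KS with estimated moments is anticonservative); if both
groups look normal at the 0.05 level a two-tailed t test is used (Welch
by default — the pooled variant sits behind `varEqual` since the choice
is not determined by the recipe), otherwise the Mann–Whitney U test,
exact when both groups have n ≤ 12 without ties and a tie-corrected,
continuity-corrected normal approximation otherwise. The
Hodges–Lehmann estimate is computed literally as the median of all
MCI − HC pairwise differences (with the distribution-free 95% CI), and
the feature screen filters at raw P < .05 — deliberately without
multiple-testing correction, to reproduce the reference analysis
faithfully; the count of significant features per task is the screen's
headline output. For n = 4 (below the closed-form Lilliefors range) the
null distribution is simulated with a fixed internal seed.

## Diagnostic models

`forwardStepwise()` implements forward selection with likelihood-ratio
entry and removal tests (entry p < .05, removal p > .10 — the classic
"Forward: LR" behavior), deterministic tie-breaks by candidate order,
and an iteration cap against entry/removal cycling. Logistic fits use
IRLS (`stats::glm`); perfect separation is flagged rather than hidden.
Odds-ratio CIs are Wald intervals on β ± 1.96·SE, exponentiated.

Performance is evaluated **in sample**, mirroring the reference
analysis; this is optimistic by construction and labelled as such.
Classification uses a 0.5 probability threshold (kept instead of a
Youden-optimal cut so that accuracy remains interpretable;
`threshold` is exposed). AUC and its CI come from pROC (DeLong); the
test suite checks the AUC against an independent concordant-pair
oracle, and the ROC against its monotonicity invariants. Cross-task
summary rows are unweighted means of sensitivity and specificity over
the drawing (T1–T6) and dragging (T7–T8) tasks, reported to 3 decimals.

The per-task candidate set is the task's applicable feature slots
(complete cases only). Per-component figure sub-scores are available
from the `ScoreReport` objects but are not in the default candidate
set.

## Stroke-order rendering

`renderPseudocolor()` encodes stroke order with colors sampled uniformly
along the viridis colormap (monotone lightness, so order reads as a
light–dark progression), later strokes overdrawing earlier ones.
Rasterization is done in-package (Bresenham lines into an RGB array,
written with `png::writePNG`) so renders are byte-identical across runs
and platforms — a property the tests assert on PNG bytes. 8-bit
quantization can collide for very large stroke counts; collisions are
resolved by a minimal deterministic blue-channel nudge that preserves
order.

## Numerical and design choices, in brief

* Times are integer milliseconds; coordinates integer pixels. The
  timeline identity above holds *exactly* on integers and is asserted,
  not approximated.
* Event streams allow in-air `move` events between strokes; a stroke
  needs no interior moves (a dot is `down`,`up`).
* Inapplicable features are `NA`, and a frequency with zero paint time
  is undefined (`NA`) rather than 0 or infinite.
* The drag task narrows the clock label set to `{number, pointer}` —
  the clock face is given, not dragged.
* Censored printed p values (`"<.001"`) are parsed as half the bound;
  any value below the bound filters identically at conventional levels.

## Simulation sizes used by the test suite

The packaged experiments use: 2000 null replicate features and 100 null
cohorts (50 per group) for type-I calibration of the screen and the
null behavior of per-task AUC; 20 replicates of the `strong` preset
(100 per group) for selection and AUC recovery; 200 random instances
per oracle-equivalence check; and 1000 generated sessions for the exact
timeline-partition identity. These sizes give binomial standard errors
small enough for the stated bands while keeping a full run on one CPU
in the minutes range.

## Known limitations

* In-sample performance estimates are optimistic; no cross-validation
  or external validation is attempted. In particular, whenever stepwise
  selection admits any variable — which under a global null still
  happens with familywise probability well above the per-test level,
  since up to 17 candidates are screened at entry p < .05 — the
  resulting in-sample AUC is upward-biased (a just-significant feature
  at 50 per group already implies AUC ≈ 0.61). Null-calibration
  experiments on selected in-sample models inherit this bias; only the
  intercept-only outcomes sit at AUC 0.5 exactly.
* The generator reproduces the *pattern* of group contrasts, not
  feature-level effect sizes from any real cohort (those are not
  recoverable from printed summaries alone).
* Component labels must be supplied; there is no recognizer.
* Discrete features (counts, rubric scores) make exact test levels
  unattainable at small n — a property of discreteness, not of the
  implementation.
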