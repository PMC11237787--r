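# inkcog

Hand-motor-function analysis of tablet "drawing and dragging" tasks for
screening mild cognitive impairment (MCI).

## What this package is for

Drawing tasks administered on a pen tablet capture *how* a figure is
produced: every pen-down, move and pen-up with millisecond timestamps.
Compared with healthy older adults, people with MCI take longer to move
the pen through the air between strokes, draw and drag more slowly,
fragment elements into more strokes, and produce lower-quality figures.
`inkcog` turns raw digitized sessions from eight tasks — the digital
Clock Drawing Test (alone and under three verbal dual-task loads), a
simplified Rey–Osterrieth Complex Figure in copy / delayed-recall /
point-and-line form, and a clock drag-and-drop task — into:

1. **17 hand-motor-function features** per session (thinking time,
   per-component painting and unpainted/in-air times, stroke and
   internal pen-lift counts, painting frequencies, rubric score), with a
   per-task applicability mask. Unpainted time charges each in-air gap
   to the upcoming stroke's component; an exact identity
   `thinking + Σ paint + Σ unpainted = t(last pen-up)` anchors the
   definitions.
2. **Rubric scores** from structured annotations: Schulman clock
   severity (1 best – 6 worst), the 9-component figure score
   (0–18 in 0.5 steps; weights 2 / 1 / 0.5 / 0), and the 0–3 drag-clock
   score.
3. **Two-group statistics** per feature: a Lilliefors-corrected
   Kolmogorov–Smirnov normality gate choosing between a two-tailed
   (Welch) t test and the Mann–Whitney U test, with the Hodges–Lehmann
   shift estimate (median of all MCI−HC pairwise differences) and its
   distribution-free 95% CI, and the raw `P < .05` feature screen.
4. **Forward-stepwise logistic diagnostic models** per task
   (likelihood-ratio entry/removal at .05/.10), with in-sample accuracy,
   sensitivity, specificity, ROC and AUC (DeLong CI), plus cross-task
   average rows.
5. **Pseudocolor stroke-order renderings** (viridis-encoded stroke
   index, byte-deterministic PNG) for qualitative inspection of drawing
   strategy.

Because no public corpus of labelled MCI pen sessions exists, the
package includes a first-class synthetic cohort generator
(`effectConfig()`, `generateCohort()`) that emulates the HC/MCI
contrasts above at configurable effect sizes, down to the annotation
layer, so the entire pipeline is testable end to end. Sessions travel
as JSON Lines (one session per line), cohorts and all result tables as
CSV.

## Worked example

```r
library(inkcog)

cfg <- effectConfig("strong", nPerGroup = c(HC = 40, MCI = 40), seed = 7)
cb  <- generateCohort(cfg, tasks = c("T1", "T6"))
ft  <- featureTable(cb)

compareAllFeatures(ft, "T6")   # feature screen, sRCFT delayed recall
td  <- taskDiagnostics(ft, "T6")
td$model
td$performance
```

Output:

```
                     feature    test_used  p_value hl_estimate significant
1 thinking_time_first_stroke mann_whitney 2.27e-01     189.000       FALSE
2          figure_paint_time            t 1.69e-08    4569.500        TRUE
3      figure_unpainted_time mann_whitney 1.64e-13    5272.500        TRUE
4        figure_total_stroke mann_whitney 1.62e-04       1.000        TRUE
5        figure_penup_stroke mann_whitney 1.62e-04       1.000        TRUE
6          figure_paint_freq mann_whitney 4.97e-06      -0.402        TRUE
7                      score mann_whitney 2.69e-07      -2.000        TRUE

StepwiseModel T6 - selected: figure_unpainted_time, score
  figure_unpainted_time        beta=  0.002 OR= 1.002 (1.001- 1.002) p=0.0003831
  score                        beta= -1.073 OR= 0.342 (0.135- 0.865) p=0.02342

DiagnosticPerformance: acc=0.950 sens=0.950 spec=0.950 auc=0.989 (0.972-1.000)
```

Reading this: the MCI group spends about 5.3 s more in the air between
strokes (Hodges–Lehmann shift of `figure_unpainted_time`, p ≈ 1.6e-13)
and scores 2 points lower on the 0–18 figure rubric; stepwise selection
keeps exactly those two features (odds ratio above 1 per ms of in-air
time, below 1 per rubric point), and the resulting model separates the
groups with in-sample AUC 0.99. In-sample metrics are optimistic by
construction — see the methods vignette (`vignettes/methods.Rmd`).

The full pipeline — simulate → score → extract → stats → classify →
render, with every table written to CSV and a hash manifest — is one
call:

```r
runPipeline(effectConfig("default"), outDir = "inkcog-out")
```

or from a shell, `Rscript inst/scripts/run_pipeline.R --preset default
--out-dir inkcog-out`.

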