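Package: inkcog
Title: Hand Motor Function Analysis of Tablet Drawing and Dragging Tasks
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for screening mild cognitive impairment (MCI) from
    digitized pen data. Provides a data model and JSON-Lines IO for
    timestamped stylus and drag event streams across eight tablet tasks
    (digital clock drawing under single and dual-task conditions, a
    simplified Rey-Osterrieth complex figure in copy, delayed-recall and
    point-and-line form, and a clock drag-and-drop task); extraction of 17
    hand-motor-function features (thinking time, per-component painting and
    in-air times, stroke and pen-lift counts, painting frequencies, rubric
    score) with a per-task applicability mask; deterministic rubric scorers
    (Schulman clock rating 1-6, 9-component figure score 0-18, drag-clock
    0-3); normality-gated two-group statistics with Hodges-Lehmann shift
    estimates; forward-stepwise logistic diagnostic models with ROC/AUC
    performance summaries; pseudocolor stroke-order rendering; and a
    synthetic cohort generator that emulates the healthy-control versus MCI
    contrasts the analysis assumes, so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    nortest,
    pROC,
    png,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
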