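Package: clockmaze
Title: Trajectory Analytics for Paddling-Pool (Clockmaze) Escape Tasks
Version: 0.1.0
Authors@R:
    person("Clockmaze", "Maintainers", email = "maintainers@clockmaze.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for rodent escape behavior in the paddling-pool
    task, a shallow-water circular arena ("clockmaze") with twelve peripheral
    holes of which one is a true exit. Reads Ethovision-style three-point
    tracks (nose, body center, tail base), computes per-trial navigation
    metrics (escape latency, decoy-inspection errors, path length, rotations,
    meander, heading-to-exit, zone dwell, occupancy maps), classifies escape
    strategies (spatial, chain, futile) from latency and error counts,
    validates the classifier with an in-house CART decision tree and feature
    ablation, derives group-level summaries (learning scores, novelty
    differences, probe-zone preference, ensemble bands, elevated-plus-maze
    ratio, rank correlations, temperature-latency fits), and ships an
    agent-based cohort simulator so the full pipeline is testable without
    animal data. A Morris-water-maze arena variant is supported for
    cross-task comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
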