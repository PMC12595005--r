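Package: loadmark
Title: Training-Load and Biomarker Monitoring for HIIT Shock Microcycles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for monitoring endurance athletes through a high-intensity
    interval training (HIIT) shock microcycle. Implements individualized
    three-zone training-impulse (TRIMP) quantification from heart-rate traces
    anchored at the 1.5 mmol/L lactate threshold and 90% of maximum heart
    rate, exponentially weighted TRIMP (3/5/7-day horizons), longitudinal
    statistics for a 32-marker blood panel (log-scale phase mixed models,
    percent change from baseline, SD noise thresholds, pre/post
    area-under-curve chronic-change analysis with group pooling),
    significance-filtered Pearson correlation rankings and networks against
    load, soreness and VO2max, and an exploratory combined log-ratio
    biomarker. A seeded synthetic-cohort generator emulates the full study
    design so every stage is testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    lmerTest,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
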