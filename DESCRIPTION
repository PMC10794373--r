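Package: vrepm
Title: Scoring and Reliability Analysis for Virtual-Reality Elevated Plus-Maze Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing human elevated plus-maze (EPM) experiments run
    in room-scale virtual reality. Head-tracking pose streams (5 Hz positions
    and orientations in the maze coordinate frame) are validated, resampled and
    scored into approach-avoidance behavioural markers (time on and entries of
    open and closed arms, latencies, path length, arm velocities), accumulated
    into cohort occupancy heatmaps, and combined with interval-averaged
    autonomic channels (skin conductance, heart rate, respiration) and salivary
    alpha-amylase triplets. A statistics layer provides test-retest reliability
    measures (Pearson correlation matrices, two-way mixed consistency
    intraclass correlations with confidence intervals), split-plot
    repeated-measures ANOVA with Greenhouse-Geisser correction and partial
    eta-squared, paired t-tests, and a priori power analysis for the paired
    t-test. A seeded agent-based simulator generates plus-maze trajectories,
    physiological series and two-exposure cohorts with known latent
    anxiety traits so that every pipeline stage can be verified end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
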