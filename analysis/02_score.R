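#!/usr/bin/env Rscript
# Stage 2: score the pose streams into behavioural markers.
#
# Reads every session listed in the cohort table, validates and resamples
# the streams to 5 Hz, and computes the approach-avoidance summary (dwell
# times, entries, latencies, distance, arm velocities) per session.

library(vrepm)

in_dir <- "results/cohort"
geom <- maze_geometry()
tab <- read.csv(file.path(in_dir, "cohort_table.csv"))

trajectories <- lapply(seq_len(nrow(tab)), function(i) {
  sess <- session_meta(tab$participant_id[i], tab$exposure[i],
                       tab$epm_version[i])
  resample_trajectory(
    read_trajectory(file.path(in_dir, tab$trajectory_file[i]), sess))
})

metrics <- score_cohort(trajectories, geom)
write.csv(metrics, "results/cohort_metrics.csv", row.names = FALSE)

cat(sprintf("scored %d sessions\n", nrow(metrics)))
for (m in c("time_open", "entries_open", "latency_first_open",
            "latency_end_exploration", "total_distance")) {
  for (e in c("first", "second")) {
    v <- metrics[metrics$exposure == e, m]
    cat(sprintf("  %-24s %-7s mean %7.2f (sd %6.2f)\n", m, e,
                mean(v), sd(v)))
  }
}
cat(sprintf("censored first-visit latencies: %d of %d sessions\n",
            sum(metrics$censored_latency_first), nrow(metrics)))
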