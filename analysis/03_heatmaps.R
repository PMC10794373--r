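#!/usr/bin/env Rscript
# Stage 3: cohort occupancy heatmaps.
#
# Accumulates each session onto the 35 x 35 grid of 10 cm bins, averages
# per exposure over participants, and builds the second-minus-first
# difference map.

library(vrepm)

in_dir <- "results/cohort"
geom <- maze_geometry()
tab <- read.csv(file.path(in_dir, "cohort_table.csv"))

maps <- lapply(seq_len(nrow(tab)), function(i) {
  sess <- session_meta(tab$participant_id[i], tab$exposure[i],
                       tab$epm_version[i])
  traj <- resample_trajectory(
    read_trajectory(file.path(in_dir, tab$trajectory_file[i]), sess))
  accumulate_occupancy(traj, geom)
})

m_first <- cohort_mean(maps[tab$exposure == "first"])
m_second <- cohort_mean(maps[tab$exposure == "second"])
m_diff <- difference_map(m_second, m_first)

write_occupancy(m_first, "results/heatmap_first.tsv")
write_occupancy(m_second, "results/heatmap_second.tsv")
write_occupancy(m_diff, "results/heatmap_difference.tsv")

print(m_first)
print(m_second)
cat(sprintf("cells with mean stay >= 0.5 s: first %d, second %d\n",
            sum(dwell_mask(m_first, 0.5)), sum(dwell_mask(m_second, 0.5))))
cat(sprintf("difference map total: %+.2f s (second minus first)\n",
            sum(m_diff$grid)))
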