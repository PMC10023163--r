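#!/usr/bin/env Rscript
# Locomotion metrics from worm centroid tracks: filtering, reversal
# detection and the per-worm / cohort summary statistics.

suppressPackageStartupMessages(library(synapsepools))
dir.create("results/locomotion", recursive = TRUE, showWarnings = FALSE)

tab <- utils::read.csv("results/synthetic/tracks.csv")
tracks <- split(tab, tab$worm_id)
kept <- filter_tracks(tracks)
ex <- attr(kept, "exclusions")
cat(sprintf("tracks: %d recorded, %d excluded (fov %d, slow %d)\n",
            length(tracks), ex$fov + ex$slow, ex$fov, ex$slow))

cm <- cohort_metrics(kept)
utils::write.csv(cm, "results/locomotion/metrics.csv", row.names = FALSE)
cat(sprintf("distance: %.1f +/- %.1f mm per 5 min\n",
            mean(cm$distance_mm), sd(cm$distance_mm) / sqrt(nrow(cm))))
cat(sprintf("speed (pauses excluded): %.1f +/- %.1f um/s\n",
            mean(cm$speed_um_s), sd(cm$speed_um_s) / sqrt(nrow(cm))))
cat(sprintf("reversals: %.1f +/- %.1f per min; reverse bout %.1f s, %.0f um\n",
            mean(cm$reversals_per_min),
            sd(cm$reversals_per_min) / sqrt(nrow(cm)),
            mean(cm$reverse_dur_s, na.rm = TRUE),
            mean(cm$reverse_dist_um, na.rm = TRUE)))
cat(sprintf("forward runs: %.1f s, %.1f mm between reversals\n",
            mean(cm$forward_run_dur_s), mean(cm$forward_run_dist_mm)))
cat("wrote results/locomotion/metrics.csv\n")
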