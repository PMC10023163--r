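#!/usr/bin/env Rscript
# Generate every synthetic input the downstream analyses consume, with
# ground-truth ledgers, and write them under results/synthetic/.

suppressPackageStartupMessages(library(synapsepools))
dir.create("results/synthetic", recursive = TRUE, showWarnings = FALSE)
seed <- 20260921

# a dorsal-cord field of view: ELKS fiducials every ~1.1 um with planted
# CaV2 / CaV1 / RyR geometry around each dense projection
cord <- simulate_cord(26, targets = geometry_targets_preset(), seed = seed)
write_localizations(cord$locs, "results/synthetic/cord_locs.csv")
cat(sprintf("cord: %d synapses, %d localizations, %d probes\n",
            nrow(cord$ledger), nrow(cord$locs),
            length(unique(cord$locs$probe))))

# well-separated fields for per-synapse geometry and colocalization: the
# dispersed CaV1/RyR clouds reach ~450 nm from their centres, so synapses
# analyzed per window must be isolated (the en-face selection in practice)
fields <- simulate_cord(26, spacing_mean_um = 3, spacing_sd_um = 0.2,
                        targets = geometry_targets_preset(), seed = seed + 1)
write_localizations(fields$locs, "results/synthetic/synapse_fields.csv")
cat(sprintf("isolated fields: %d synapses, %d localizations\n",
            nrow(fields$ledger), nrow(fields$locs)))

# miniature-current amplitudes under both pharmacology presets
for (preset in c("nemadipine", "dantrolene_nemadipine")) {
  m <- simulate_minis(quantal_preset(preset), 2e4, seed = seed)
  utils::write.csv(data.frame(amplitude_pA = m$amplitudes,
                              true_class = m$classes),
                   sprintf("results/synthetic/minis_%s.csv", preset),
                   row.names = FALSE)
  cat(sprintf("minis (%s): %d events, %d truncated at 0\n",
              preset, length(m$amplitudes), m$n_truncated))
}

# docked-vesicle tables for each genotype-like depletion pattern
for (g in c("wild_type", "cav2_null", "ryr_null", "cav1_hypo",
            "cav1_cav2_null")) {
  vp <- simulate_vesicle_profiles(120, depletion = em_depletion_preset(g),
                                  genotype = g, seed = seed)
  tab <- rbind(vp$no_stim, vp$stim)
  utils::write.csv(tab, sprintf("results/synthetic/docked_%s.csv", g),
                   row.names = FALSE)
  cat(sprintf("docked (%s): %d vesicles over %d synapses/condition\n",
              g, nrow(tab), vp$ledger$n_synapses))
}

# worm tracks near wild-type crawling
tr <- simulate_tracks(12, seed = seed)
utils::write.csv(do.call(rbind, tr$tracks), "results/synthetic/tracks.csv",
                 row.names = FALSE)
utils::write.csv(tr$ledger, "results/synthetic/tracks_ledger.csv",
                 row.names = FALSE)
cat(sprintf("tracks: %d worms x %d frames\n", length(tr$tracks),
            nrow(tr$tracks[[1]])))
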