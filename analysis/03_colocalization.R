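#!/usr/bin/env Rscript
# Nearest-neighbour colocalization between the dispersed probes: for each
# RyR localization the distance to the closest CaV1 localization (and the
# reverse), pooled over synapse windows.

suppressPackageStartupMessages(library(synapsepools))
dir.create("results/colocalization", recursive = TRUE, showWarnings = FALSE)

locs <- filter_precision(flatten_z(
  read_localizations("results/synthetic/synapse_fields.csv")))
rois <- segment_rois(locs, "ELKS")

all_d <- list()
for (pair in list(c("RyR", "CaV1"), c("CaV1", "RyR"))) {
  nn <- nn_summary(rois, pair[1], pair[2], threshold = 100)
  cat(sprintf("%s -> %s: %d distances over %d synapses; %.0f%% within 100 nm (median %.0f nm)\n",
              pair[1], pair[2], nrow(nn$distances), nrow(nn$per_roi),
              100 * nn$fraction_within, median(nn$distances$distance_nm)))
  d <- nn$distances; d$source <- pair[1]; d$target <- pair[2]
  all_d[[paste(pair, collapse = "_")]] <- d
}
utils::write.csv(do.call(rbind, all_d),
                 "results/colocalization/nn_distances.csv", row.names = FALSE)
cat("wrote results/colocalization/nn_distances.csv\n")
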