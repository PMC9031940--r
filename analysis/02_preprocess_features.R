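#!/usr/bin/env Rscript
# Preprocess the study recording and extract the feature matrix:
# high-pass + notch filtering, 2-s epoching (50% ictal overlap), 9:1
# rebalancing, five-band decomposition, per-channel/band fs1 features,
# and correlation pruning at |r| > 0.95. Writes results/features.csv.

source("analysis/00_config.R")

rec <- read_recording(file.path(results_dir, "study_recording.tsv"))
pc <- study_preprocess_config()

filtered <- filter_recording(rec, pc)
es <- segment_epochs(filtered, pc)
cat(sprintf("segmented: %d epochs (%d ictal, %d non-ictal)\n",
            length(es$labels), sum(es$labels), sum(es$labels == 0)))

es <- rebalance(es, pc)
cat(sprintf("rebalanced to %d epochs (ratio %.1f:1 non-ictal:ictal)\n",
            length(es$labels), sum(es$labels == 0) / sum(es$labels)))

esb <- band_decompose(es, pc)
fm <- extract_features(esb, study_feature_config())
cat(sprintf("extracted %d features (%d bands x %d channels x 8 metrics)\n",
            ncol(fm$values), length(esb$band_names),
            length(esb$channel_names)))

pruned <- prune_correlated(fm, study_feature_config()$corr_threshold)
cat(sprintf("pruning removed %d correlated features; %d remain\n",
            length(pruned$dropped), ncol(pruned$fm$values)))

write_feature_matrix(pruned$fm, file.path(results_dir, "features.csv"))
cat("wrote", file.path(results_dir, "features.csv"), "\n")
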