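#!/usr/bin/env Rscript
# Rank features with the six methods (decision-tree Gini, linear-SVM
# weights, LIME, kernel SHAP, RF permutation importance, reciprocal rank
# fusion), paired with the random-forest classifier. Writes one ranking CSV
# per method plus a top-10 report, and checks the planted features.

source("analysis/00_config.R")

fm <- read_feature_matrix(file.path(results_dir, "features.csv"))
rks <- compute_rankings(fm, study_classifier(), study_fsm_config())

gt <- intersect(ground_truth_features(study_synth_config(), "fs1"),
                colnames(fm$values))
cat(sprintf("%d planted features survive pruning\n", length(gt)))

top10 <- list()
for (m in names(rks)) {
  write_ranking(rks[[m]], file.path(results_dir,
                                    sprintf("ranking_%s.csv", m)))
  rep10 <- top_features_report(rks[[m]], 10)
  rep10$method <- m
  top10[[m]] <- rep10
  hits <- intersect(rep10$feature_name, gt)
  cat(sprintf("%-5s top feature: %-28s planted in top-10: %d\n",
              m, rep10$feature_name[1], length(hits)))
}
write.csv(do.call(rbind, top10), file.path(results_dir, "top10_features.csv"),
          row.names = FALSE)
cat("wrote per-method ranking CSVs and results/top10_features.csv\n")
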