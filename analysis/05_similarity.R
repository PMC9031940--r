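#!/usr/bin/env Rscript
# Feature-set agreement between ranking methods: pairwise Jaccard indices
# of the top-k selected features at several cutoffs. Writes one similarity
# matrix CSV per cutoff.

source("analysis/00_config.R")

methods <- c("dt", "svm", "lime", "shap", "erf", "rr")
rks <- lapply(methods, function(m) {
  df <- read.csv(file.path(results_dir, sprintf("ranking_%s.csv", m)))
  new_ranking(stats::setNames(df$score, df$feature_name), m)
})
names(rks) <- methods

p <- length(rks[[1]]$scores)
cutoffs <- unique(pmin(c(150, 100, 50, 25), p))
for (k in cutoffs) {
  sm <- pairwise_similarity(rks, k)
  write_similarity(sm, file.path(results_dir,
                                 sprintf("similarity_k%d.csv", k)))
  offdiag <- sm$values[upper.tri(sm$values)]
  cat(sprintf("k=%3d: Jaccard range %.2f-%.2f, mean %.2f\n",
              k, min(offdiag), max(offdiag), mean(offdiag)))
}
cat("wrote per-cutoff similarity matrices under results/\n")
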