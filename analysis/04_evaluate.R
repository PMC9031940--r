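#!/usr/bin/env Rscript
# Stepwise feature elimination under 5x2 cross-validation: every ranking is
# evaluated with the random forest along the elimination schedule (steps of
# 50 plus 25/12/6/1), and the best method per feature count is compared to
# the rest with the 5x2cv F-test. Writes elimination curves and F-test
# tables. This is the long step (several hundred classifier fits).

source("analysis/00_config.R")

fm <- read_feature_matrix(file.path(results_dir, "features.csv"))
clf <- study_classifier()
methods <- c("dt", "svm", "lime", "shap", "erf", "rr")
rks <- lapply(methods, function(m) {
  df <- read.csv(file.path(results_dir, sprintf("ranking_%s.csv", m)))
  new_ranking(stats::setNames(df$score, df$feature_name), m)
})
names(rks) <- methods

schedule <- elimination_schedule(ncol(fm$values))
cat("elimination schedule:", schedule, "\n")

rows <- list()
results <- list()
for (m in methods) {
  for (k in schedule) {
    ev <- run_5x2cv(fm, rks[[m]], k, clf, seed = study_seed + 4)
    results[[sprintf("%s_%d", m, k)]] <- ev
    rows[[length(rows) + 1]] <- data.frame(
      fsm = m, n_features = k, f1 = ev$f1,
      sensitivity = ev$sensitivity, accuracy = ev$accuracy)
    cat(sprintf("%-5s k=%4d  F1=%.3f Se=%.3f Acc=%.3f\n",
                m, k, ev$f1, ev$sensitivity, ev$accuracy))
  }
}
curves <- do.call(rbind, rows)
write.csv(curves, file.path(results_dir, "elimination_curves.csv"),
          row.names = FALSE)

# F-test: best method per feature count against the others
ft_rows <- list()
for (k in schedule) {
  at_k <- curves[curves$n_features == k, ]
  best <- at_k$fsm[which.max(at_k$f1)]
  for (m in setdiff(at_k$fsm, best)) {
    ft <- f_test_5x2cv(results[[sprintf("%s_%d", best, k)]]$errors,
                       results[[sprintf("%s_%d", m, k)]]$errors)
    ft_rows[[length(ft_rows) + 1]] <- data.frame(
      n_features = k, best_fsm = best, other_fsm = m,
      F = ft$F, p = ft$p, significant = ft$significant)
  }
}
ftests <- do.call(rbind, ft_rows)
write.csv(ftests, file.path(results_dir, "ftest_tables.csv"),
          row.names = FALSE)
cat(sprintf("%d of %d F-tests significant at 0.05\n",
            sum(ftests$significant), nrow(ftests)))
cat("wrote results/elimination_curves.csv and results/ftest_tables.csv\n")
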