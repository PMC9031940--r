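#' Pipeline configuration
#'
#' Bundles every stage configuration. The global seed deterministically
#' derives per-stage sub-seeds, so a rerun with the same config is
#' bit-identical for every deterministic stage.
#'
#' @param synth A [synth_config()].
#' @param preprocess A [preprocess_config()].
#' @param features A [feature_config()].
#' @param fsm An [fsm_config()].
#' @param classifiers Named or unnamed list of [classifier_config()]s.
#' @param schedule Optional feature-count schedule override; defaults to
#'   [elimination_schedule()] of the post-pruning feature count.
#' @param similarity_k Subset size(s) for the Jaccard comparison; defaults
#'   to the schedule values at or below 50 plus the largest schedule entry.
#' @param seed Global integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_config(),
                            preprocess = preprocess_config(),
                            features = feature_config(),
                            fsm = fsm_config(),
                            classifiers = list(RF = classifier_config("RF")),
                            schedule = NULL, similarity_k = NULL,
                            seed = 1L) {
  seed <- as.integer(seed)
  synth$seed <- derive_seed(seed, 1L)
  preprocess$seed <- derive_seed(seed, 2L)
  fsm$seed <- derive_seed(seed, 3L)
  for (i in seq_along(classifiers)) {
    classifiers[[i]]$seed <- derive_seed(seed, 10L + i)
  }
  if (is.null(names(classifiers))) {
    names(classifiers) <- vapply(classifiers, `[[`, "", "kind")
  }
  structure(list(synth = synth, preprocess = preprocess, features = features,
                 fsm = fsm, classifiers = classifiers, schedule = schedule,
                 similarity_k = similarity_k, seed = seed),
            class = "pipeline_config")
}

# Derived sub-seeds stay below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647L)
}

#' Compute all six feature rankings for one classifier pairing
#'
#' Draws a seeded stratified subsample (default 50%) of the feature matrix,
#' min-max scales it, and computes: decision-tree Gini importance, linear-SVM
#' weights, LIME and kernel SHAP (both explaining a classifier of the paired
#' evaluation family, trained on the subsample), random-forest permutation
#' importance (holdout = the rows outside the subsample), and the reciprocal
#' rank fusion of those five.
#'
#' @param fm A [feature_matrix()].
#' @param clf A [classifier_config()] naming the paired classifier family.
#' @param config An [fsm_config()].
#' @return Named list of [new_ranking()]s: dt, svm, lime, shap, erf, rr.
#' @export
compute_rankings <- function(fm, clf, config = fsm_config()) {
  stopifnot(inherits(fm, "feature_matrix"))
  y <- fm$labels
  set.seed(config$seed)
  sub <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    sub <- c(sub, sample(idx, max(1, round(length(idx) *
                                             config$ranking_subsample_fraction))))
  }
  sub <- sort(sub)
  rest <- setdiff(seq_along(y), sub)
  if (length(rest) < 2 || length(unique(y[rest])) < 2) rest <- sub

  sc <- minmax_scale(fm$values[sub, , drop = FALSE],
                     fm$values[rest, , drop = FALSE])
  Xs <- sc$train; ys <- y[sub]
  Xh <- sc$test; yh <- y[rest]

  ref_model <- fit_classifier(Xs, ys, clf)
  rks <- list(
    dt = rank_dt_gini(Xs, ys, config),
    svm = rank_svm_weights(Xs, ys, config),
    lime = rank_lime(Xs, ys, ref_model, config),
    shap = rank_kernel_shap(Xs, ys, ref_model, config),
    erf = rank_erf_permutation(Xs, ys, config, Xh, yh)
  )
  rks$rr <- reciprocal_rank_fusion(rks)
  rks
}

cache_fetch <- function(dir, key, compute) {
  path <- file.path(dir, paste0(key, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  value <- compute()
  saveRDS(value, path)
  value
}

#' Run the full evaluation pipeline
#'
#' Simulate -> preprocess -> extract and prune features -> rank (six methods
#' per classifier) -> evaluate under 5x2 CV along the elimination schedule ->
#' F-test the best method against the rest -> feature-set similarity.
#' Artifacts (CSV tables, ranking files, a JSON manifest echoing the resolved
#' configuration) are written under `out_dir`; stages are cached by config
#' hash, so a rerun with one changed classifier does not recompute features.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the manifest and in-memory results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cache_dir <- file.path(out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list())
  stage <- function(name, cfg, compute) {
    key <- paste0(name, "-", rlang::hash(cfg))
    manifest$stages[[name]] <<- key
    tryCatch(cache_fetch(cache_dir, key, compute),
             error = function(e) {
               jsonlite::write_json(manifest,
                                    file.path(out_dir, "manifest.json"),
                                    auto_unbox = TRUE)
               stop("pipeline stage '", name, "' failed: ",
                    conditionMessage(e), call. = FALSE)
             })
  }

  rec <- stage("simulate", config$synth,
               function() generate_recording(config$synth))
  pre_cfg <- list(synth = config$synth, pre = config$preprocess)
  es <- stage("preprocess", pre_cfg, function() {
    filtered <- filter_recording(rec, config$preprocess)
    segs <- segment_epochs(filtered, config$preprocess)
    segs <- rebalance(segs, config$preprocess)
    band_decompose(segs, config$preprocess)
  })
  feat_cfg <- c(pre_cfg, list(feat = config$features))
  feat <- stage("features", feat_cfg, function() {
    fm <- extract_features(es, config$features)
    pruned <- prune_correlated(fm, config$features$corr_threshold)
    write_feature_matrix(pruned$fm, file.path(out_dir, "features.csv"))
    pruned
  })
  fm <- feat$fm
  p <- ncol(fm$values)
  schedule <- config$schedule
  if (is.null(schedule)) schedule <- elimination_schedule(p)
  schedule <- schedule[schedule <= p]

  rankings <- list()
  results <- list()
  ftests <- list()
  for (cname in names(config$classifiers)) {
    clf <- config$classifiers[[cname]]
    rk_cfg <- c(feat_cfg, list(fsm = config$fsm, clf = clf))
    rks <- stage(paste0("rank_", cname), rk_cfg,
                 function() compute_rankings(fm, clf, config$fsm))
    rankings[[cname]] <- rks
    for (m in names(rks)) {
      write_ranking(rks[[m]], file.path(out_dir,
                                        sprintf("ranking_%s_%s.csv",
                                                cname, m)))
    }
    ev_cfg <- c(rk_cfg, list(schedule = schedule))
    res <- stage(paste0("evaluate_", cname), ev_cfg, function() {
      out <- list()
      for (m in names(rks)) {
        for (k in schedule) {
          out[[length(out) + 1]] <-
            run_5x2cv(fm, rks[[m]], k, clf,
                      seed = derive_seed(config$seed, 100L))
        }
      }
      out
    })
    results[[cname]] <- res
    ftests[[cname]] <- stage(paste0("ftest_", cname), ev_cfg,
                             function() ftest_table(res))
  }

  curve <- do.call(rbind, lapply(unlist(results, recursive = FALSE),
                                 function(r) {
    data.frame(classifier = r$classifier, fsm = r$fsm,
               n_features = r$n_features, f1 = r$f1,
               sensitivity = r$sensitivity, accuracy = r$accuracy)
  }))
  utils::write.csv(curve, file.path(out_dir, "elimination_curves.csv"),
                   row.names = FALSE)
  ft_all <- do.call(rbind, ftests)
  if (!is.null(ft_all)) {
    utils::write.csv(ft_all, file.path(out_dir, "ftest_tables.csv"),
                     row.names = FALSE)
  }

  sim_k <- config$similarity_k
  if (is.null(sim_k)) {
    sim_k <- unique(c(max(schedule), schedule[schedule <= 50 & schedule > 1]))
  }
  sims <- list()
  for (cname in names(rankings)) {
    for (k in sim_k) {
      sm <- pairwise_similarity(rankings[[cname]], k)
      sims[[sprintf("%s_k%d", cname, k)]] <- sm
      write_similarity(sm, file.path(out_dir,
                                     sprintf("similarity_%s_k%d.csv",
                                             cname, k)))
    }
  }

  manifest$epochs <- length(fm$labels)
  manifest$ictal_epochs <- sum(fm$labels)
  manifest$features_pre_pruning <- p + length(feat$dropped)
  manifest$features_post_pruning <- p
  manifest$features_dropped <- length(feat$dropped)
  manifest$schedule <- schedule
  manifest$classifiers <- names(config$classifiers)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(manifest = manifest, feature_matrix = fm,
                 rankings = rankings, results = results,
                 similarity = sims, ftests = ftests))
}

# Best FSM (by F1) per feature count, F-tested against every other FSM at
# the same feature count.
ftest_table <- function(results) {
  df <- data.frame(idx = seq_along(results),
                   fsm = vapply(results, `[[`, "", "fsm"),
                   k = vapply(results, `[[`, 0, "n_features"),
                   f1 = vapply(results, `[[`, 0, "f1"))
  out <- list()
  for (k in unique(df$k)) {
    at_k <- df[df$k == k, ]
    best <- at_k[which.max(at_k$f1), ]
    for (i in seq_len(nrow(at_k))) {
      if (at_k$idx[i] == best$idx) next
      ft <- f_test_5x2cv(results[[best$idx]]$errors,
                         results[[at_k$idx[i]]]$errors)
      out[[length(out) + 1]] <- data.frame(
        classifier = results[[best$idx]]$classifier, n_features = k,
        best_fsm = best$fsm, other_fsm = at_k$fsm[i],
        F = ft$F, p = ft$p, significant = ft$significant)
    }
  }
  do.call(rbind, out)
}
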