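#' Feature-selection method configuration
#'
#' Settings of the six importance-ranking methods. Defaults: single decision
#' tree (Gini, min node size 4); linear SVM with C = 1; LIME with 1000
#' Gaussian perturbations per instance, exponential kernel of width
#' `0.75 * sqrt(M)`, no discretization; kernel SHAP with a 50-centroid
#' k-means background, full coalition enumeration up to 12 features and
#' `2M + 2048` sampled coalitions beyond; permutation importance on a random
#' forest of 10 trees (min node size 2) with 5 permutation repeats on a
#' holdout set. Model training during ranking uses a seeded stratified 50%
#' subsample of the data.
#'
#' @param dt,svm,lime,shap,erf Per-method parameter lists (see Details in
#'   the ranking functions); partial overrides are merged into defaults.
#' @param ranking_subsample_fraction Fraction of the data used when model
#'   training is required during ranking (default 0.5).
#' @param seed Integer seed driving every stochastic ranking step.
#' @return An `fsm_config` list.
#' @export
fsm_config <- function(dt = list(), svm = list(), lime = list(),
                       shap = list(), erf = list(),
                       ranking_subsample_fraction = 0.5, seed = 1L) {
  stopifnot(ranking_subsample_fraction > 0, ranking_subsample_fraction <= 1)
  merge_in <- function(defaults, user) {
    defaults[names(user)] <- user
    defaults
  }
  structure(list(
    dt = merge_in(list(min_samples = 4L), dt),
    svm = merge_in(list(cost = 1), svm),
    lime = merge_in(list(n_samples = 1000L, kernel_width = NULL,
                         n_explain = 25L), lime),
    shap = merge_in(list(background_size = 50L, max_enum = 12L,
                         n_coalitions = NULL, n_explain = 10L), shap),
    erf = merge_in(list(n_trees = 10L, min_samples = 2L, repeats = 5L), erf),
    ranking_subsample_fraction = ranking_subsample_fraction,
    seed = as.integer(seed)
  ), class = "fsm_config")
}

#' Construct a feature ranking
#'
#' Scores are forced non-negative (absolute-value convention) and the
#' induced order sorts scores non-increasingly; ties are broken stably by
#' original column position.
#'
#' @param scores Named numeric vector of importances.
#' @param method Method identifier string.
#' @return A `ranking` object with fields `scores`, `order`, `method`,
#'   `tie_policy`.
#' @export
new_ranking <- function(scores, method) {
  stopifnot(!is.null(names(scores)), !anyDuplicated(names(scores)),
            all(is.finite(scores)))
  scores <- abs(scores)
  o <- order(-scores, seq_along(scores))
  structure(list(scores = scores, order = names(scores)[o], method = method,
                 tie_policy = "stable by original column index"),
            class = "ranking")
}

#' @export
print.ranking <- function(x, ...) {
  cat(sprintf("<ranking:%s> %d features; top: %s\n", x$method,
              length(x$scores),
              paste(utils::head(x$order, 3), collapse = ", ")))
  invisible(x)
}

check_two_classes <- function(y) {
  if (length(unique(y)) < 2) stop("labels contain a single class")
}

# rpart chokes on non-syntactic feature names (bipolar labels contain "-"),
# so trees are always fitted on positional aliases.
safe_names <- function(p) paste0("V", seq_len(p))

#' Decision-tree Gini importance ranking
#'
#' Fits one CART tree (Gini impurity, minimum node size from the config) and
#' scores each feature as the sum over the nodes split on it of
#' `p(t) * delta_i(t)`, where `p(t)` is the fraction of training samples
#' reaching the node and `delta_i` the impurity decrease of its split.
#' Scores are normalized to sum to 1; features never used in a split score 0.
#'
#' @param X Feature matrix (rows = epochs).
#' @param y Binary labels.
#' @param config An [fsm_config()].
#' @return A [new_ranking()] with method `"dt"`.
#' @export
rank_dt_gini <- function(X, y, config = fsm_config()) {
  check_two_classes(y)
  feat_names <- colnames(X)
  Xs <- X
  colnames(Xs) <- safe_names(ncol(X))
  df <- data.frame(Xs, y = factor(y, levels = c(0, 1)))
  fit <- rpart::rpart(y ~ ., data = df, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        minsplit = config$dt$min_samples, minbucket = 1,
                        cp = 0, maxcompete = 0, maxsurrogate = 0, xval = 0))
  imp <- gini_importance_from_rpart(fit, ncol(X))
  names(imp) <- feat_names
  if (sum(imp) > 0) imp <- imp / sum(imp)
  new_ranking(imp, "dt")
}

# Walk the fitted tree: node numbers double down each level, so the children
# of node t are 2t and 2t + 1; class counts per node sit in frame$yval2.
gini_importance_from_rpart <- function(fit, p) {
  frame <- fit$frame
  nn <- as.integer(rownames(frame))
  counts <- frame$yval2[, 2:3, drop = FALSE]
  nreach <- frame$n
  N <- nreach[1]
  gini <- 1 - rowSums((counts / nreach)^2)
  imp <- stats::setNames(rep(0, p), safe_names(p))
  internal <- which(frame$var != "<leaf>")
  for (i in internal) {
    l <- match(2L * nn[i], nn)
    r <- match(2L * nn[i] + 1L, nn)
    drop <- (nreach[i] * gini[i] - nreach[l] * gini[l] -
               nreach[r] * gini[r]) / N
    v <- as.character(frame$var[i])
    imp[v] <- imp[v] + drop
  }
  imp
}

#' Linear-SVM weight ranking
#'
#' Fits a soft-margin linear SVM (C from the config) on min-max-scaled data
#' and ranks features by the absolute hyperplane weights.
#'
#' @inheritParams rank_dt_gini
#' @return A [new_ranking()] with method `"svm"`.
#' @export
rank_svm_weights <- function(X, y, config = fsm_config()) {
  check_two_classes(y)
  fit <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "linear",
                    cost = config$svm$cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  new_ranking(stats::setNames(abs(w)[colnames(X)], colnames(X)), "svm")
}

#' Per-instance importance aggregation
#'
#' Takes absolute values per instance first, then averages per feature
#' (abs-then-mean), so opposite-signed local attributions never cancel.
#'
#' @param per_instance Instances x features numeric matrix.
#' @return Named per-feature score vector.
#' @export
aggregate_instance_importance <- function(per_instance) {
  stopifnot(is.matrix(per_instance), nrow(per_instance) >= 1)
  colMeans(abs(per_instance))
}

pick_explained <- function(n, n_explain) {
  if (is.null(n_explain) || n_explain >= n) seq_len(n)
  else sort(sample.int(n, n_explain))
}

#' LIME-style surrogate ranking
#'
#' For each explained instance, draws Gaussian perturbations around it
#' (per-feature scale = the training standard deviation), weights them with
#' the exponential kernel `exp(-d^2 / width^2)` on Euclidean distance, fits a
#' weighted linear surrogate to the model's positive-class probability, and
#' takes coefficient magnitudes. Per-instance scores are aggregated
#' abs-then-mean.
#'
#' @param X Min-max-scaled feature matrix (the ranking subsample).
#' @param y Binary labels (unused beyond validation; the surrogate explains
#'   the model, not the labels).
#' @param model Fitted classifier from [fit_classifier()] exposing
#'   probability output.
#' @param config An [fsm_config()].
#' @return A [new_ranking()] with method `"lime"`.
#' @export
rank_lime <- function(X, y, model, config = fsm_config()) {
  stopifnot(inherits(model, "ictalfs_model"))
  M <- ncol(X)
  width <- config$lime$kernel_width
  if (is.null(width)) width <- 0.75 * sqrt(M)
  ns <- config$lime$n_samples
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1e-12
  set.seed(config$seed)
  rows <- pick_explained(nrow(X), config$lime$n_explain)
  per_inst <- matrix(0, length(rows), M, dimnames = list(NULL, colnames(X)))
  for (ii in seq_along(rows)) {
    x0 <- X[rows[ii], ]
    Z <- matrix(stats::rnorm(ns * M), ns, M) *
      matrix(sds, ns, M, byrow = TRUE) +
      matrix(x0, ns, M, byrow = TRUE)
    Z[1, ] <- x0
    colnames(Z) <- colnames(X)
    fz <- predict_classifier(model, Z, type = "prob")
    d2 <- rowSums((Z - matrix(x0, ns, M, byrow = TRUE))^2)
    w <- exp(-d2 / width^2)
    coefs <- stats::lm.wfit(cbind(1, Z), fz, w)$coefficients[-1]
    coefs[is.na(coefs)] <- 0
    per_inst[ii, ] <- coefs
  }
  new_ranking(aggregate_instance_importance(per_inst), "lime")
}

shapley_kernel_weight <- function(M, s) {
  (M - 1) / (choose(M, s) * s * (M - s))
}

# Solve the Shapley-kernel weighted least squares under the additive
# constraint sum(phi) = fx - phi0, by eliminating the last coefficient.
solve_kernel_shap <- function(Z, v, w, phi0, fx) {
  M <- ncol(Z)
  delta <- fx - phi0
  if (M == 1) return(delta)
  A <- Z[, -M, drop = FALSE] - Z[, M]
  rhs <- v - phi0 - Z[, M] * delta
  fit <- stats::lm.wfit(A, rhs, w)
  phi <- fit$coefficients
  phi[is.na(phi)] <- 0
  c(phi, delta - sum(phi))
}

# Model output for coalitions: features in the coalition take the explained
# instance's values, absent features are imputed from each background
# centroid; the value is the mean output over all centroids.
coalition_values <- function(Z, x0, background, model, chunk = 256L) {
  nb <- nrow(background)
  M <- ncol(Z)
  out <- numeric(nrow(Z))
  for (start in seq(1, nrow(Z), by = chunk)) {
    idx <- start:min(start + chunk - 1, nrow(Z))
    big <- background[rep(seq_len(nb), times = length(idx)), , drop = FALSE]
    zrep <- Z[rep(idx, each = nb), , drop = FALSE]
    xrep <- matrix(x0, nrow(big), M, byrow = TRUE)
    big[zrep == 1] <- xrep[zrep == 1]
    colnames(big) <- names(x0)
    f <- predict_classifier(model, big, type = "prob")
    out[idx] <- colMeans(matrix(f, nrow = nb))
  }
  out
}

#' Kernel SHAP attribution of one instance
#'
#' Solves the Shapley-kernel weighted regression for a single explained
#' instance against an explicit background matrix. With full enumeration
#' (feature count at most `max_enum`) the result equals the exact Shapley
#' values of the background-imputed value function.
#'
#' @param model Fitted classifier from [fit_classifier()].
#' @param x0 Named numeric vector, the instance to explain (scaled space).
#' @param background Matrix of background rows (e.g. k-means centroids).
#' @param max_enum Full-enumeration limit (default 12).
#' @param n_coalitions Coalition budget beyond full enumeration; default
#'   `2M + 2048`.
#' @return Numeric attribution vector (signed), one value per feature, with
#'   the background mean prediction as attribute `"phi0"`.
#' @export
kernel_shap_explain <- function(model, x0, background, max_enum = 12L,
                                n_coalitions = NULL) {
  M <- length(x0)
  if (nrow(background) < 1) stop("empty background set")
  colnames(background) <- names(x0)
  phi0 <- mean(predict_classifier(model, background, type = "prob"))
  fx <- predict_classifier(model,
                           matrix(x0, 1, dimnames = list(NULL, names(x0))),
                           type = "prob")
  if (M == 1) {
    out <- fx - phi0
    attr(out, "phi0") <- phi0
    return(out)
  }
  Z <- shap_coalitions(M, max_enum, n_coalitions)
  w <- shapley_kernel_weight(M, rowSums(Z))
  v <- coalition_values(Z, x0, background, model)
  phi <- solve_kernel_shap(Z, v, w, phi0, fx)
  names(phi) <- names(x0)
  attr(phi, "phi0") <- phi0
  phi
}

shap_coalitions <- function(M, max_enum, n_coalitions) {
  if (M <= max_enum) {
    Z <- as.matrix(expand.grid(rep(list(0:1), M)))[, seq_len(M), drop = FALSE]
    sizes <- rowSums(Z)
    Z <- Z[sizes > 0 & sizes < M, , drop = FALSE]
  } else {
    if (is.null(n_coalitions)) n_coalitions <- 2L * M + 2048L
    n_extra <- max(0L, n_coalitions - 2L * M)
    sz_support <- seq_len(M - 1)
    sz_prob <- (M - 1) / (sz_support * (M - sz_support))
    szs <- sample(sz_support, n_extra, replace = TRUE,
                  prob = sz_prob / sum(sz_prob))
    Zr <- t(vapply(szs, function(s) {
      z <- numeric(M); z[sample.int(M, s)] <- 1; z
    }, numeric(M)))
    Z <- rbind(diag(M), 1 - diag(M), Zr)
  }
  storage.mode(Z) <- "double"
  unname(Z)
}

#' Kernel SHAP ranking
#'
#' Additive feature attributions from a Shapley-kernel weighted linear
#' regression over feature coalitions. Absent features are imputed by
#' averaging the model output over a k-means background (50 centroids by
#' default) computed from the data. Coalitions are fully enumerated when the
#' feature count is at most `max_enum` (in which case the attributions equal
#' exact Shapley values of the coalition value function), otherwise
#' `2M + 2048` coalitions are used: every singleton and every
#' leave-one-out coalition, plus coalitions sampled from the Shapley-kernel
#' size distribution. Per-instance attributions are aggregated abs-then-mean.
#'
#' @inheritParams rank_lime
#' @return A [new_ranking()] with method `"shap"`. The per-instance
#'   attribution matrix is attached as attribute `"per_instance"` and
#'   satisfies local accuracy under full enumeration.
#' @export
rank_kernel_shap <- function(X, y, model, config = fsm_config()) {
  stopifnot(inherits(model, "ictalfs_model"))
  M <- ncol(X)
  set.seed(config$seed)
  bg_n <- min(config$shap$background_size, nrow(unique(X)))
  if (bg_n < 1) stop("empty background set")
  background <- if (bg_n < nrow(unique(X))) {
    stats::kmeans(X, centers = bg_n, iter.max = 50, nstart = 1)$centers
  } else {
    unique(X)
  }
  colnames(background) <- colnames(X)
  rows <- pick_explained(nrow(X), config$shap$n_explain)
  per_inst <- matrix(0, length(rows), M, dimnames = list(NULL, colnames(X)))
  phi0 <- NA_real_
  for (ii in seq_along(rows)) {
    phi <- kernel_shap_explain(model, X[rows[ii], ], background,
                               config$shap$max_enum,
                               config$shap$n_coalitions)
    phi0 <- attr(phi, "phi0")
    per_inst[ii, ] <- as.numeric(phi)
  }
  rk <- new_ranking(aggregate_instance_importance(per_inst), "shap")
  attr(rk, "per_instance") <- per_inst
  attr(rk, "explained_rows") <- rows
  attr(rk, "phi0") <- phi0
  rk
}

#' Random-forest permutation importance ranking
#'
#' Trains a random forest (10 trees, min node size 2 by default) on the
#' ranking subsample and scores each feature by the mean increase in
#' misclassification rate on a separate holdout set when that feature's
#' holdout column is permuted, averaged over the configured number of
#' repeats. Negative increases are clipped by the absolute-value convention.
#'
#' @inheritParams rank_dt_gini
#' @param holdout_X,holdout_y Holdout data disjoint from `X`.
#' @return A [new_ranking()] with method `"erf"`.
#' @export
rank_erf_permutation <- function(X, y, config = fsm_config(),
                                 holdout_X, holdout_y) {
  check_two_classes(y)
  check_two_classes(holdout_y)
  set.seed(config$seed)
  fit <- randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                    ntree = config$erf$n_trees,
                                    nodesize = config$erf$min_samples)
  base_pred <- as.integer(as.character(stats::predict(fit, holdout_X)))
  base_err <- mean(base_pred != holdout_y)
  p <- ncol(X)
  scores <- numeric(p)
  nh <- nrow(holdout_X)
  for (j in seq_len(p)) {
    inc <- numeric(config$erf$repeats)
    for (r in seq_len(config$erf$repeats)) {
      Xp <- holdout_X
      Xp[, j] <- Xp[sample.int(nh), j]
      pred <- as.integer(as.character(stats::predict(fit, Xp)))
      inc[r] <- mean(pred != holdout_y) - base_err
    }
    scores[j] <- mean(inc)
  }
  new_ranking(stats::setNames(scores, colnames(X)), "erf")
}

#' Reciprocal rank fusion
#'
#' Merges ranked lists into one: each feature's fused value is
#' `r(f) = 1 / sum_j(1 / r_j(f))` over its 1-based rank positions in the
#' input rankings; smaller fused values are better. The returned ranking
#' stores `1 / r(f)` (the sum of reciprocal ranks) as its score, so the
#' usual descending-score ordering applies.
#'
#' @param rankings List of [new_ranking()] objects over the identical
#'   feature set.
#' @return A [new_ranking()] with method `"rr"`; fused values are attached
#'   as attribute `"fused_value"`.
#' @export
reciprocal_rank_fusion <- function(rankings) {
  stopifnot(length(rankings) >= 1)
  feats <- names(rankings[[1]]$scores)
  for (rk in rankings) {
    if (!setequal(names(rk$scores), feats)) {
      stop("rankings cover different feature sets")
    }
  }
  recip_sum <- stats::setNames(rep(0, length(feats)), feats)
  for (rk in rankings) {
    pos <- match(feats, rk$order)
    recip_sum <- recip_sum + 1 / pos
  }
  out <- new_ranking(recip_sum, "rr")
  attr(out, "fused_value") <- 1 / recip_sum
  out
}

#' Write a ranking to CSV with a JSON config sidecar
#'
#' @param rk A [new_ranking()].
#' @param path CSV output path (columns feature_name, score, rank); a
#'   `<path>.json` sidecar echoes method and tie policy.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(rk, path) {
  pos <- match(names(rk$scores), rk$order)
  df <- data.frame(feature_name = names(rk$scores), score = rk$scores,
                   rank = pos)
  df <- df[order(df$rank), ]
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(method = rk$method, tie_policy = rk$tie_policy),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
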