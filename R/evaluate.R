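#' Min-max scaling fitted on the training split
#'
#' Per-feature affine map to `[0, 1]` fitted on the training rows only and
#' applied to both splits; test values outside the training range are left
#' outside `[0, 1]` (no clipping). A constant training feature maps to 0
#' everywhere.
#'
#' @param train_X,test_X Numeric matrices with identical columns; `test_X`
#'   may be `NULL`.
#' @return List with `train`, `test` and the fitted `min`/`range` vectors.
#' @export
minmax_scale <- function(train_X, test_X = NULL) {
  stopifnot(nrow(train_X) >= 2)
  mins <- apply(train_X, 2, min)
  rng <- apply(train_X, 2, max) - mins
  scale_one <- function(X) {
    out <- sweep(X, 2, mins)
    for (j in seq_len(ncol(out))) {
      out[, j] <- if (rng[j] > 0) out[, j] / rng[j] else 0
    }
    out
  }
  list(train = scale_one(train_X),
       test = if (!is.null(test_X)) scale_one(test_X),
       min = mins, range = rng)
}

#' Stepwise feature-elimination schedule
#'
#' Starting from all features: every positive multiple of 50 strictly below
#' the feature count, descending, then 25, 12, 6 and 1; duplicates removed.
#'
#' @param n_features Total feature count.
#' @return Strictly decreasing integer vector starting at `n_features` and
#'   ending at 1.
#' @export
elimination_schedule <- function(n_features) {
  stopifnot(n_features >= 1)
  fifties <- seq_len(floor((n_features - 1) / 50)) * 50
  out <- unique(c(n_features, rev(fifties), 25, 12, 6, 1))
  out[out <= n_features]
}

#' Classification metrics from confusion counts
#'
#' Sensitivity (recall of the positive class), F1 (harmonic mean of
#' precision and sensitivity) and accuracy. Zero-denominator cases return 0.
#'
#' @param tp,fp,fn,tn Non-negative confusion counts.
#' @return Named list: f1, sensitivity, accuracy.
#' @export
classification_metrics <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0, tp + fp + fn + tn > 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  list(f1 = f1, sensitivity = sens,
       accuracy = (tp + tn) / (tp + fp + fn + tn))
}

stratified_two_fold <- function(y) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    half <- ceiling(length(idx) / 2)
    fold[idx[seq_len(half)]] <- 1L
    fold[idx[-seq_len(half)]] <- 2L
  }
  fold
}

#' 5x2 cross-validated evaluation of a ranked feature subset
#'
#' Keeps the top `k` features of the ranking, then runs five repetitions of
#' stratified two-fold cross-validation: each repetition reshuffles the data
#' (seeded), splits it in two, trains on either fold and tests on the other.
#' Min-max scaling is fitted on the training fold only. Records the 10
#' per-fold error rates and fold-averaged F1 / sensitivity / accuracy, with
#' the ictal (minority) class as positive.
#'
#' @param fm A [feature_matrix()].
#' @param ranking A [new_ranking()] covering `fm`'s features, or `NULL` to
#'   keep all features in their native order.
#' @param k Number of top-ranked features to keep.
#' @param clf A [classifier_config()].
#' @param seed Integer seed for the fold shuffles.
#' @return An `eval_result` list: `errors` (5 x 2 matrix), `f1`,
#'   `sensitivity`, `accuracy` (fold averages), `n_features`, `classifier`,
#'   `fsm`.
#' @export
run_5x2cv <- function(fm, ranking = NULL, k = NULL, clf, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  feats <- colnames(fm$values)
  if (!is.null(ranking)) {
    stopifnot(all(feats %in% names(ranking$scores)),
              all(ranking$order %in% feats))
    sel <- ranking$order
  } else {
    sel <- feats
  }
  if (is.null(k)) k <- length(sel)
  stopifnot(k >= 1, k <= length(sel))
  X <- fm$values[, sel[seq_len(k)], drop = FALSE]
  y <- fm$labels

  errors <- matrix(0, 5, 2)
  mets <- matrix(0, 10, 3)
  row <- 0
  set.seed(seed)
  for (rep_i in 1:5) {
    fold <- stratified_two_fold(y)
    for (fold_j in 1:2) {
      tr <- fold == fold_j
      te <- !tr
      sc <- minmax_scale(X[tr, , drop = FALSE], X[te, , drop = FALSE])
      model <- fit_classifier(sc$train, y[tr], clf)
      pred <- predict_classifier(model, sc$test, type = "class")
      truth <- y[te]
      errors[rep_i, fold_j] <- mean(pred != truth)
      m <- classification_metrics(sum(pred == 1 & truth == 1),
                                  sum(pred == 1 & truth == 0),
                                  sum(pred == 0 & truth == 1),
                                  sum(pred == 0 & truth == 0))
      row <- row + 1
      mets[row, ] <- c(m$f1, m$sensitivity, m$accuracy)
    }
  }
  structure(list(errors = errors, f1 = mean(mets[, 1]),
                 sensitivity = mean(mets[, 2]), accuracy = mean(mets[, 3]),
                 n_features = k, classifier = clf$kind,
                 fsm = if (!is.null(ranking)) ranking$method else "none"),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s/%s k=%d: F1 %.3f, Se %.3f, Acc %.3f\n",
              x$classifier, x$fsm, x$n_features, x$f1, x$sensitivity,
              x$accuracy))
  invisible(x)
}

#' Combined 5x2cv F-test for comparing two classifiers
#'
#' For fold-wise error differences `d_ij = errA_ij - errB_ij` and
#' per-repetition variances `s_i^2`, the statistic
#' `F = sum(d_ij^2) / (2 * sum(s_i^2))` is referred to the F distribution
#' with (10, 5) degrees of freedom. Both error grids must come from the same
#' fold partitions. If every repetition variance is zero while differences
#' are non-zero the comparison is flagged degenerate (p = 0); if all
#' differences are zero, F = 0 and p = 1.
#'
#' @param errors_a,errors_b 5 x 2 error-rate matrices.
#' @param alpha Significance level (default 0.05).
#' @return List: `F`, `p`, `significant`, `degenerate`.
#' @export
f_test_5x2cv <- function(errors_a, errors_b, alpha = 0.05) {
  stopifnot(all(dim(errors_a) == c(5, 2)), all(dim(errors_b) == c(5, 2)))
  d <- errors_a - errors_b
  num <- sum(d^2)
  s2 <- apply(d, 1, stats::var)
  den <- 2 * sum(s2)
  if (num == 0) {
    return(list(F = 0, p = 1, significant = FALSE, degenerate = FALSE))
  }
  if (den == 0) {
    return(list(F = Inf, p = 0, significant = TRUE, degenerate = TRUE))
  }
  f <- num / den
  p <- stats::pf(f, 10, 5, lower.tail = FALSE)
  list(F = f, p = p, significant = p < alpha, degenerate = FALSE)
}

# Midpoint-threshold stump on one feature: the lightest classifier with
# honest sampling variability, used for null calibration of the F-test.
stump_errors_5x2 <- function(X, y, feature_a, feature_b) {
  errs_a <- matrix(0, 5, 2)
  errs_b <- matrix(0, 5, 2)
  stump_err <- function(xtr, ytr, xte, yte) {
    thr <- (mean(xtr[ytr == 1]) + mean(xtr[ytr == 0])) / 2
    up <- mean(xtr[ytr == 1]) >= mean(xtr[ytr == 0])
    pred <- if (up) as.integer(xte >= thr) else as.integer(xte < thr)
    mean(pred != yte)
  }
  for (rep_i in 1:5) {
    fold <- stratified_two_fold(y)
    for (fold_j in 1:2) {
      tr <- fold == fold_j
      errs_a[rep_i, fold_j] <- stump_err(X[tr, feature_a], y[tr],
                                         X[!tr, feature_a], y[!tr])
      errs_b[rep_i, fold_j] <- stump_err(X[tr, feature_b], y[tr],
                                         X[!tr, feature_b], y[!tr])
    }
  }
  list(a = errs_a, b = errs_b)
}

#' Null rejection rate of the 5x2cv F-test by simulation
#'
#' Simulates dataset pairs under the null of equal expected accuracy: two
#' identically distributed, equally informative features; classifier A
#' thresholds feature 1, classifier B thresholds feature 2, both inside the
#' same 5x2 CV partitions. Returns the fraction of simulations rejected at
#' `alpha`, which should sit near `alpha` for a calibrated test.
#'
#' @param n_sims Number of simulated dataset pairs (default 500).
#' @param n Samples per dataset (default 120).
#' @param effect Class separation of each informative feature in SD units
#'   (default 1).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed.
#' @return List: `rejection_rate`, `n_sims`.
#' @export
ftest_null_rejection <- function(n_sims = 500, n = 120, effect = 1,
                                 alpha = 0.05, seed = 1L) {
  set.seed(seed)
  rejections <- logical(n_sims)
  for (s in seq_len(n_sims)) {
    y <- rep(c(0L, 1L), length.out = n)
    X <- cbind(stats::rnorm(n, mean = effect * y),
               stats::rnorm(n, mean = effect * y))
    grids <- stump_errors_5x2(X, y, 1, 2)
    rejections[s] <- f_test_5x2cv(grids$a, grids$b, alpha)$significant
  }
  list(rejection_rate = mean(rejections), n_sims = n_sims)
}
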