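#' Classifier configuration
#'
#' Fixed per-feature-set configurations of the five evaluated classifier
#' kinds. Defaults follow the package's tuned settings: decision tree (Gini,
#' minimum node size 8 for fs1, 2 for fs2), RBF-kernel SVM (C = 2, gamma =
#' 1 / (n_features x var(X))), K-nearest neighbours (fs1: k = 15, Manhattan,
#' uniform votes; fs2: k = 10, Euclidean, inverse-distance votes), random
#' forest (150 trees, node size 4), and a feed-forward network trained for
#' 200 epochs with entropy loss.
#'
#' @param model One of `"DT"`, `"SVM"`, `"KNN"`, `"RF"`, `"ANN"`.
#' @param feature_set `"fs1"` or `"fs2"` (selects the tuned variant).
#' @param seed Seed used for stochastic fitters (RF, ANN).
#' @param ... Overrides for individual parameters (e.g. `k`, `n_trees`).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(model = c("DT", "SVM", "KNN", "RF", "ANN"),
                              feature_set = c("fs1", "fs2"), seed = 1L, ...) {
  kind <- match.arg(model)
  feature_set <- match.arg(feature_set)
  params <- switch(kind,
    DT = list(min_samples = if (feature_set == "fs1") 8L else 2L),
    SVM = list(cost = 2, kernel = "radial", gamma = "scale"),
    KNN = if (feature_set == "fs1") {
      list(k = 15L, metric = "manhattan", weights = "uniform")
    } else {
      list(k = 10L, metric = "euclidean", weights = "distance")
    },
    RF = list(n_trees = 150L, min_samples = 4L),
    ANN = list(hidden = 50L, maxit = 200L)
  )
  override <- list(...)
  params[names(override)] <- override
  structure(list(kind = kind, feature_set = feature_set, params = params,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Fit a classifier on a (scaled) feature matrix
#'
#' @param X Numeric matrix, rows = epochs (min-max scaled).
#' @param y Binary labels (1 = ictal).
#' @param config A [classifier_config()].
#' @return A fitted model wrapper for [predict_classifier()].
#' @export
fit_classifier <- function(X, y, config) {
  stopifnot(inherits(config, "classifier_config"), nrow(X) == length(y))
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  y <- factor(y, levels = c(0, 1))
  p <- config$params
  set.seed(config$seed)
  fit <- switch(config$kind,
    DT = {
      df <- data.frame(X, y = y, check.names = FALSE)
      rpart::rpart(y ~ ., data = df, method = "class",
                   parms = list(split = "gini"),
                   control = rpart::rpart.control(
                     minsplit = p$min_samples, minbucket = 1, cp = 0,
                     maxcompete = 0, maxsurrogate = 0, xval = 0))
    },
    SVM = {
      gamma <- if (identical(p$gamma, "scale")) {
        v <- stats::var(as.vector(X))
        if (v <= 0) 1 / ncol(X) else 1 / (ncol(X) * v)
      } else p$gamma
      e1071::svm(X, y, kernel = p$kernel, cost = p$cost, gamma = gamma,
                 scale = FALSE, probability = TRUE)
    },
    KNN = list(X = X, y = y, k = p$k, metric = p$metric,
               weights = p$weights),
    RF = randomForest::randomForest(X, y, ntree = p$n_trees,
                                    nodesize = p$min_samples),
    ANN = {
      nw <- (ncol(X) + 1) * p$hidden + (p$hidden + 1)
      nnet::nnet(X, as.numeric(as.character(y)), size = p$hidden,
                 entropy = TRUE, maxit = p$maxit, MaxNWts = nw + 1,
                 trace = FALSE)
    }
  )
  structure(list(kind = config$kind, fit = fit, config = config),
            class = "ictalfs_model")
}

# Cross-distance matrix between test rows and train rows.
cross_dist <- function(A, B, metric) {
  if (metric == "euclidean") {
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
    sqrt(pmax(d2, 0))
  } else {
    out <- matrix(0, nrow(A), nrow(B))
    for (i in seq_len(nrow(A))) {
      out[i, ] <- colSums(abs(t(B) - A[i, ]))
    }
    out
  }
}

knn_prob <- function(model, X) {
  D <- cross_dist(X, model$X, model$metric)
  ytr <- as.integer(as.character(model$y))
  k <- model$k
  vapply(seq_len(nrow(X)), function(i) {
    o <- order(D[i, ])[seq_len(k)]
    if (model$weights == "distance") {
      w <- 1 / pmax(D[i, o], 1e-12)
      sum(w * ytr[o]) / sum(w)
    } else {
      mean(ytr[o])
    }
  }, numeric(1))
}

#' Wrap an arbitrary probability function as a model
#'
#' Builds a model object whose positive-class probability is computed by
#' `predict_fun(X)`. Useful for explaining analytically defined models (the
#' explanation methods are model-agnostic) and for oracle checks.
#'
#' @param predict_fun Function taking a numeric matrix and returning the
#'   positive-class probability per row.
#' @return An `ictalfs_model` usable with [predict_classifier()].
#' @export
custom_model <- function(predict_fun) {
  stopifnot(is.function(predict_fun))
  structure(list(kind = "CUSTOM", fit = predict_fun, config = NULL),
            class = "ictalfs_model")
}

#' Predict with a fitted classifier
#'
#' @param model A model from [fit_classifier()].
#' @param X Numeric matrix on the same (scaled) feature space.
#' @param type `"class"` for hard 0/1 labels or `"prob"` for the
#'   positive-class (ictal) probability/score in `[0, 1]`.
#' @return Integer labels or numeric probabilities.
#' @export
predict_classifier <- function(model, X, type = c("class", "prob")) {
  type <- match.arg(type)
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  prob <- switch(model$kind,
    DT = stats::predict(model$fit,
                        data.frame(X, check.names = FALSE))[, "1"],
    SVM = {
      pr <- attr(stats::predict(model$fit, X, probability = TRUE),
                 "probabilities")
      pr[, "1"]
    },
    KNN = knn_prob(model$fit, X),
    RF = stats::predict(model$fit, X, type = "prob")[, "1"],
    ANN = as.vector(stats::predict(model$fit, X)),
    CUSTOM = as.numeric(model$fit(X))
  )
  prob <- unname(prob)
  if (type == "prob") prob else as.integer(prob >= 0.5)
}
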