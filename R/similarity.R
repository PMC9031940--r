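#' Jaccard index of two feature sets
#'
#' `|a intersect b| / |a union b|`. Undefined (error) when both sets are
#' empty.
#'
#' @param a,b Character vectors (treated as sets).
#' @return Value in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) {
    stop("Jaccard index undefined for two empty sets")
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Pairwise Jaccard similarity of top-k feature sets
#'
#' Takes the top `k` features of each ranking and computes all pairwise
#' Jaccard indices. The result is symmetric with unit diagonal.
#'
#' @param rankings Named list of [new_ranking()] objects over the same
#'   feature universe.
#' @param k Subset size (at most the universe size).
#' @return A `similarity_matrix` object: `methods`, `k`, `values`.
#' @export
pairwise_similarity <- function(rankings, k) {
  stopifnot(length(rankings) >= 2)
  universe <- names(rankings[[1]]$scores)
  for (rk in rankings) stopifnot(setequal(names(rk$scores), universe))
  stopifnot(k >= 1, k <= length(universe))
  methods <- names(rankings)
  if (is.null(methods)) methods <- vapply(rankings, `[[`, "", "method")
  tops <- lapply(rankings, function(rk) utils::head(rk$order, k))
  m <- length(tops)
  values <- matrix(1, m, m, dimnames = list(methods, methods))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      values[i, j] <- values[j, i] <- jaccard(tops[[i]], tops[[j]])
    }
  }
  structure(list(methods = methods, k = k, values = values),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> k=%d\n", x$k))
  print(round(x$values, 2))
  invisible(x)
}

#' Top-feature report for a ranking
#'
#' The `n` best features with their raw (unnormalized) importance values,
#' in ranking order, named `"band_channel_metric"`.
#'
#' @param ranking A [new_ranking()].
#' @param n Number of features to report (default 10).
#' @return Data frame with `feature_name` and `importance`.
#' @export
top_features_report <- function(ranking, n = 10) {
  stopifnot(n >= 1, n <= length(ranking$scores))
  feats <- utils::head(ranking$order, n)
  data.frame(feature_name = feats,
             importance = unname(ranking$scores[feats]))
}

#' Write a similarity matrix to CSV
#'
#' @param sm A [pairwise_similarity()] result.
#' @param path Output path; method names form the header and first column.
#' @param digits Rounding applied at presentation (default 2).
#' @return `path`, invisibly.
#' @export
write_similarity <- function(sm, path, digits = 2) {
  utils::write.csv(round(sm$values, digits), path, row.names = TRUE)
  invisible(path)
}
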