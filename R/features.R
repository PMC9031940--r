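#' Feature extraction configuration
#'
#' @param feature_set `"fs1"` (spectral/shape statistics: median frequency,
#'   variance, skewness, kurtosis, peak frequency, RMS, range, zero
#'   crossings) or `"fs2"` (minimum, Hjorth complexity and mobility,
#'   interquartile range, median absolute deviation, sample entropy, mean,
#'   standard deviation).
#' @param sampen_m Sample-entropy template length (default 2).
#' @param sampen_r_coeff Sample-entropy tolerance as a multiple of the epoch
#'   standard deviation (default 0.2).
#' @param corr_threshold Absolute Pearson correlation above which one of a
#'   feature pair is pruned (default 0.95).
#' @return A validated `feature_config` list.
#' @export
feature_config <- function(feature_set = c("fs1", "fs2"), sampen_m = 2L,
                           sampen_r_coeff = 0.2, corr_threshold = 0.95) {
  feature_set <- match.arg(feature_set)
  stopifnot(sampen_m >= 1, corr_threshold > 0, corr_threshold <= 1)
  structure(list(feature_set = feature_set, sampen_m = as.integer(sampen_m),
                 sampen_r_coeff = sampen_r_coeff,
                 corr_threshold = corr_threshold),
            class = "feature_config")
}

feature_metric_names <- function(feature_set) {
  switch(feature_set,
    fs1 = c("medfreq", "var", "skew", "kurt", "peakfreq", "rms", "range", "zc"),
    fs2 = c("min", "complexity", "mobility", "iqr", "mad", "sampen",
            "mean", "sd"),
    stop("unknown feature set: ", feature_set)
  )
}

#' Time-domain amplitude statistics of one epoch
#'
#' Skewness and kurtosis use moment-ratio definitions (kurtosis is excess:
#' a normal epoch scores near 0); for a constant epoch both are defined as 0
#' so no NaN ever propagates. Zero crossings count strict sign changes
#' between consecutive samples; an exact zero inherits the previous sign so
#' a touch of the axis is never double-counted.
#'
#' @param x Numeric vector (one epoch, one channel).
#' @return Named list: variance, skewness, kurtosis, rms, range,
#'   zero_crossings, minimum, mean, sd, iqr, mad.
#' @export
amplitude_stats <- function(x) {
  stopifnot(length(x) >= 2)
  mu <- mean(x)
  v <- stats::var(x)
  m2 <- mean((x - mu)^2)
  if (m2 > 0) {
    skew <- mean((x - mu)^3) / m2^1.5
    kurt <- mean((x - mu)^4) / m2^2 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  list(variance = v, skewness = skew, kurtosis = kurt,
       rms = sqrt(mean(x^2)), range = max(x) - min(x),
       zero_crossings = count_zero_crossings(x), minimum = min(x),
       mean = mu, sd = sqrt(v),
       iqr = unname(stats::quantile(x, 0.75) - stats::quantile(x, 0.25)),
       mad = stats::mad(x, constant = 1))
}

count_zero_crossings <- function(x) {
  s <- sign(x)
  # exact zeros inherit the previous sign
  if (any(s == 0)) {
    for (i in seq_along(s)) {
      if (s[i] == 0) s[i] <- if (i > 1) s[i - 1] else 1
    }
  }
  sum(s[-1] != s[-length(s)])
}

#' Spectral metrics of one epoch
#'
#' The power spectral density is a single Hann-windowed periodogram of the
#' full epoch (0.5 Hz resolution for 2-s epochs at 256 Hz). Median frequency
#' is the smallest frequency at which cumulative power reaches half of the
#' total; peak frequency is the PSD argmax. A zero-power epoch returns 0 for
#' both by convention.
#'
#' @param x Numeric vector (one epoch, one channel).
#' @param fs Sampling rate in Hz.
#' @return Named list: median_frequency, peak_frequency.
#' @export
spectral_metrics <- function(x, fs) {
  stopifnot(length(x) >= 4)
  psd <- hann_periodogram(matrix(x, nrow = 1), fs)
  median_peak_from_psd(psd$power[1, ], psd$freq)
}

hann_periodogram <- function(xmat, fs) {
  ns <- ncol(xmat)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(ns) / (ns + 1)))
  xw <- sweep(xmat, 2, w, `*`)
  spec <- stats::mvfft(t(xw))
  half <- floor(ns / 2) + 1
  power <- t(Mod(spec[seq_len(half), , drop = FALSE])^2)
  freq <- (seq_len(half) - 1) * fs / ns
  list(power = power, freq = freq)
}

median_peak_from_psd <- function(p, freq) {
  tot <- sum(p)
  if (tot <= 0) return(list(median_frequency = 0, peak_frequency = 0))
  cum <- cumsum(p)
  list(median_frequency = freq[which(cum >= tot / 2)[1]],
       peak_frequency = freq[which.max(p)])
}

#' Hjorth mobility and complexity
#'
#' Mobility is `sqrt(var(diff(x)) / var(x))`, a discrete measure of mean
#' frequency; complexity is the mobility of the first difference divided by
#' the mobility of the signal, a measure of frequency change. A constant
#' epoch returns (0, 0) by convention.
#'
#' @param x Numeric vector (one epoch, one channel).
#' @return Named list: mobility, complexity.
#' @export
hjorth_params <- function(x) {
  v0 <- stats::var(x)
  if (v0 == 0) return(list(mobility = 0, complexity = 0))
  d1 <- diff(x)
  v1 <- stats::var(d1)
  mob <- sqrt(v1 / v0)
  if (v1 == 0) return(list(mobility = mob, complexity = 0))
  v2 <- stats::var(diff(d1))
  list(mobility = mob, complexity = sqrt(v2 / v1) / mob)
}

#' Sample entropy
#'
#' SampEn(m, r) = -ln(A/B) with B the number of length-`m` template pairs
#' within Chebyshev tolerance `r = r_coeff * sd(x)` (self-matches excluded)
#' and A the same count for length m+1. If no pair matches at either length
#' the value is capped at `log(length(x))`. With `sd(x) = 0` the tolerance is
#' 0 and equal samples count as matching, so a constant epoch scores 0.
#'
#' @param x Numeric vector, longer than `m + 1`.
#' @param m Template length (default 2).
#' @param r_coeff Tolerance coefficient (default 0.2).
#' @return Non-negative scalar.
#' @export
sample_entropy <- function(x, m = 2L, r_coeff = 0.2) {
  if (length(x) <= m + 1) stop("epoch too short for sample entropy")
  r <- r_coeff * stats::sd(x)
  .sampen_cpp(as.numeric(x), as.integer(m), r)
}

#' Feature matrix container
#'
#' @param values n_epochs x n_features numeric matrix with
#'   `"band_channel_metric"` column names.
#' @param labels Binary label vector (1 = ictal).
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(values, labels) {
  stopifnot(is.matrix(values), nrow(values) == length(labels),
            !is.null(colnames(values)), !anyDuplicated(colnames(values)),
            all(is.finite(values)))
  structure(list(values = values, labels = as.integer(labels)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d epochs (%d ictal) x %d features\n",
              nrow(x$values), sum(x$labels), ncol(x$values)))
  invisible(x)
}

#' Extract per-channel per-band features from a band-decomposed epoch set
#'
#' One column per (band, channel, metric), named `"band_channel_metric"`
#' (e.g. `"alpha_FP1-F3_skew"`). Column order is band-major, then channel,
#' then metric, and deterministic.
#'
#' @param es A band-decomposed [epoch_set()].
#' @param config A [feature_config()].
#' @return A [feature_matrix()].
#' @export
extract_features <- function(es, config) {
  stopifnot(inherits(es, "epoch_set"), is.list(es$epochs))
  metrics <- feature_metric_names(config$feature_set)
  n <- length(es$labels)
  cols <- list()
  for (band in es$band_names) {
    arr <- es$epochs[[band]]
    for (ch in seq_along(es$channel_names)) {
      x <- arr[, ch, , drop = TRUE]
      if (n == 1) x <- matrix(x, nrow = 1)
      block <- epoch_block_features(x, es$fs, config)
      colnames(block) <- paste(band, es$channel_names[ch],
                               colnames(block), sep = "_")
      cols[[length(cols) + 1]] <- block[, paste(band, es$channel_names[ch],
                                                metrics, sep = "_"),
                                        drop = FALSE]
    }
  }
  feature_matrix(do.call(cbind, cols), es$labels)
}

# Vectorized computation of all metrics of one feature set for a block of
# epochs (rows) on a single channel/band.
epoch_block_features <- function(x, fs, config) {
  n <- nrow(x); ns <- ncol(x)
  mu <- rowMeans(x)
  cx <- x - mu
  m2 <- rowMeans(cx^2)
  v <- m2 * ns / (ns - 1)
  if (config$feature_set == "fs1") {
    psd <- hann_periodogram(x, fs)
    spect <- t(vapply(seq_len(n), function(i) {
      s <- median_peak_from_psd(psd$power[i, ], psd$freq)
      c(s$median_frequency, s$peak_frequency)
    }, numeric(2)))
    skew <- ifelse(m2 > 0, rowMeans(cx^3) / m2^1.5, 0)
    kurt <- ifelse(m2 > 0, rowMeans(cx^4) / m2^2 - 3, 0)
    zc <- vapply(seq_len(n), function(i) count_zero_crossings(x[i, ]),
                 numeric(1))
    out <- cbind(medfreq = spect[, 1], var = v, skew = skew, kurt = kurt,
                 peakfreq = spect[, 2], rms = sqrt(rowMeans(x^2)),
                 range = apply(x, 1, max) - apply(x, 1, min), zc = zc)
  } else {
    d1 <- x[, -1, drop = FALSE] - x[, -ns, drop = FALSE]
    d2 <- d1[, -1, drop = FALSE] - d1[, -(ns - 1), drop = FALSE]
    v1 <- apply(d1, 1, stats::var)
    v2 <- apply(d2, 1, stats::var)
    mob <- ifelse(v > 0, sqrt(v1 / v), 0)
    comp <- ifelse(v > 0 & v1 > 0, sqrt(v2 / v1) / mob, 0)
    qs <- apply(x, 1, stats::quantile, probs = c(0.25, 0.75))
    se <- vapply(seq_len(n), function(i) {
      sample_entropy(x[i, ], config$sampen_m, config$sampen_r_coeff)
    }, numeric(1))
    out <- cbind(min = apply(x, 1, min), complexity = comp, mobility = mob,
                 iqr = qs[2, ] - qs[1, ],
                 mad = apply(x, 1, stats::mad, constant = 1),
                 sampen = se, mean = mu, sd = sqrt(v))
  }
  out
}

#' Prune highly correlated features
#'
#' Greedy scan in column order: column `j` is dropped when its absolute
#' Pearson correlation with any earlier retained column exceeds the
#' threshold, so of each offending pair the later column goes. Zero-variance
#' columns correlate with nothing, are retained, and are reported in the
#' audit attribute. The operation is idempotent.
#'
#' @param fm A [feature_matrix()] with at least 3 rows.
#' @param threshold Absolute correlation threshold (default 0.95).
#' @return List with `fm` (the pruned [feature_matrix()]), `dropped`
#'   (character vector of removed names) and `zero_variance` (audit list of
#'   constant columns).
#' @export
prune_correlated <- function(fm, threshold = 0.95) {
  stopifnot(inherits(fm, "feature_matrix"), nrow(fm$values) >= 3)
  X <- fm$values
  sds <- apply(X, 2, stats::sd)
  zerovar <- colnames(X)[sds == 0]
  cm <- suppressWarnings(abs(stats::cor(X)))
  cm[is.na(cm)] <- 0
  p <- ncol(X)
  keep <- rep(TRUE, p)
  for (j in seq_len(p)[-1]) {
    earlier <- which(keep[seq_len(j - 1)])
    if (length(earlier) > 0 && any(cm[earlier, j] > threshold)) {
      keep[j] <- FALSE
    }
  }
  list(fm = feature_matrix(X[, keep, drop = FALSE], fm$labels),
       dropped = colnames(X)[!keep], zero_variance = zerovar)
}

#' Write a feature matrix to CSV
#'
#' One row per epoch; feature columns by name plus a final `label` column.
#'
#' @param fm A [feature_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.table::as.data.table(fm$values)
  df$label <- fm$labels
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV path.
#' @return A [feature_matrix()].
#' @export
read_feature_matrix <- function(path) {
  df <- as.data.frame(data.table::fread(path), check.names = FALSE)
  if (!"label" %in% names(df)) stop("feature CSV lacks a 'label' column")
  labels <- df$label
  df$label <- NULL
  feature_matrix(as.matrix(df), labels)
}
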