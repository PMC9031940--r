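#' Default bipolar channel labels (longitudinal "double banana" montage)
#'
#' Returns the standard 10-20 longitudinal bipolar derivations. The first 18
#' labels are the classic double-banana chains; three additional temporal
#' derivations (as found in pediatric scalp recordings that keep 21 bipolar
#' channels) extend the list to 21.
#'
#' @param n Number of labels requested (at most 21).
#' @return Character vector of `n` bipolar labels such as `"FP1-F3"`.
#' @export
default_bipolar_labels <- function(n = 21) {
  labs <- c(
    "FP1-F7", "F7-T7", "T7-P7", "P7-O1",
    "FP1-F3", "F3-C3", "C3-P3", "P3-O1",
    "FP2-F4", "F4-C4", "C4-P4", "P4-O2",
    "FP2-F8", "F8-T8", "T8-P8", "P8-O2",
    "FZ-CZ", "CZ-PZ",
    "T7-FT9", "FT9-FT10", "FT10-T8"
  )
  if (n > length(labs)) {
    # beyond the named montage, fall back to generic labels
    labs <- c(labs, sprintf("CH%d-REF", seq_len(n - length(labs))))
  }
  labs[seq_len(n)]
}

#' Configuration for the synthetic EEG generator
#'
#' Describes an annotated multichannel scalp EEG recording with planted
#' ictal structure. Background activity on every channel is 1/f colored
#' noise plus a modest alpha-range oscillation, so that all five analysis
#' bands carry non-degenerate power. Seizures superimpose a higher-amplitude
#' rhythmic component on the channels named in `ictal_spec`, which makes a
#' known set of channel/band amplitude features genuinely discriminative.
#'
#' @param n_channels Number of bipolar channels (default 21).
#' @param fs Sampling rate in Hz (default 256).
#' @param duration Recording length in seconds.
#' @param n_seizures Number of seizure intervals to plant.
#' @param seizure_duration Mean seizure length in seconds.
#' @param seizure_jitter Half-width of the uniform jitter on seizure length.
#' @param background List with `noise_sd` (microvolt scale of the 1/f
#'   background), `alpha_amp` and `alpha_hz` (amplitude and frequency of the
#'   background oscillation).
#' @param ictal_spec Data frame with columns `channel` (1-based index),
#'   `band` (one of `"delta"`, `"theta"`, `"alpha"`, `"beta"`), `gain`
#'   (amplitude in microvolts of the planted rhythm) and `freq_hz`
#'   (its frequency, which must lie inside the named band).
#' @param channel_names Optional channel labels; defaults to the double-banana
#'   montage labels.
#' @param min_gap Minimum spacing in seconds between seizures (default 4,
#'   i.e. twice the 2-s analysis window, so no epoch straddles two seizures).
#' @param seed Integer seed; identical configs give bit-identical recordings.
#' @return A `synth_config` list, validated.
#' @export
synth_config <- function(n_channels = 21, fs = 256, duration = 3600,
                         n_seizures = 4, seizure_duration = 30,
                         seizure_jitter = 5,
                         background = list(noise_sd = 20, alpha_amp = 8,
                                           alpha_hz = 10),
                         ictal_spec = data.frame(
                           channel = 1L, band = "delta",
                           gain = 60, freq_hz = 3
                         ),
                         channel_names = NULL, min_gap = 4, seed = 1L) {
  stopifnot(n_channels >= 1, fs > 0, duration > 0, n_seizures >= 0,
            seizure_duration > 0, seizure_jitter >= 0,
            seizure_jitter < seizure_duration)
  n_samples <- duration * fs
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    stop("duration x fs must be an integer sample count")
  }
  if (is.null(channel_names)) channel_names <- default_bipolar_labels(n_channels)
  stopifnot(length(channel_names) == n_channels)
  if (nrow(ictal_spec) > 0) {
    stopifnot(all(c("channel", "band", "gain", "freq_hz") %in%
                    names(ictal_spec)))
    if (any(ictal_spec$channel < 1 | ictal_spec$channel > n_channels)) {
      stop("ictal_spec channel index out of range")
    }
    if (!all(ictal_spec$band %in% c("delta", "theta", "alpha", "beta"))) {
      stop("ictal_spec band must be one of delta/theta/alpha/beta")
    }
  }
  structure(list(
    n_channels = as.integer(n_channels), fs = fs, duration = duration,
    n_seizures = as.integer(n_seizures),
    seizure_duration = seizure_duration, seizure_jitter = seizure_jitter,
    background = background, ictal_spec = ictal_spec,
    channel_names = channel_names, min_gap = min_gap,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' Construct a recording object
#'
#' @param data Channels x samples numeric matrix (microvolts).
#' @param fs Sampling rate in Hz.
#' @param channel_names Channel labels, one per row of `data`.
#' @param seizures Data frame with `start_s`, `end_s` (half-open intervals,
#'   seconds), ordered and non-overlapping.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, fs, channel_names,
                          seizures = data.frame(start_s = numeric(0),
                                                end_s = numeric(0))) {
  stopifnot(is.matrix(data), nrow(data) == length(channel_names))
  if (nrow(seizures) > 0) {
    stopifnot(all(seizures$end_s > seizures$start_s),
              all(seizures$start_s >= 0),
              all(seizures$end_s <= ncol(data) / fs + 1e-9))
    o <- order(seizures$start_s)
    seizures <- seizures[o, , drop = FALSE]
    if (any(utils::head(seizures$end_s, -1) >
            utils::tail(seizures$start_s, -1) + 1e-9)) {
      stop("seizure intervals overlap")
    }
  }
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 seizures = seizures), class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d seizure(s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$seizures)))
  invisible(x)
}

# 1/f colored noise of length n: shape white noise in the frequency domain
# so that power ~ 1/f (amplitude ~ f^-1/2), DC term zeroed.
colored_noise <- function(n, sd_target) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  freqs <- c(1, seq_len(n - 1))          # avoid dividing by zero at DC
  half <- floor(n / 2)
  f <- pmin(freqs - 1, n - (freqs - 1))  # symmetric frequency index
  f[1] <- 0
  amp <- ifelse(f == 0, 0, 1 / sqrt(f))
  x <- Re(stats::fft(spec * amp, inverse = TRUE)) / n
  x * sd_target / stats::sd(x)
}

# Place n_seizures intervals with the given durations inside [0, duration]
# keeping at least min_gap seconds between consecutive intervals.
place_seizures <- function(durations, duration, min_gap) {
  n <- length(durations)
  if (n == 0) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  slack <- duration - sum(durations) - (n - 1) * min_gap
  if (slack < 0) {
    stop("infeasible seizure placement: total seizure time plus spacing ",
         "exceeds recording duration")
  }
  # distribute the slack across n + 1 gaps via sorted uniform spacings
  cuts <- sort(stats::runif(n))
  gaps <- diff(c(0, cuts, 1)) * slack
  starts <- numeric(n)
  pos <- 0
  for (i in seq_len(n)) {
    pos <- pos + gaps[i]
    starts[i] <- pos
    pos <- pos + durations[i] + min_gap
  }
  data.frame(start_s = starts, end_s = starts + durations)
}

band_limits <- function() {
  list(complete = c(0.5, 30), delta = c(0.5, 4), theta = c(4, 8),
       alpha = c(8, 12), beta = c(12, 25))
}

#' Generate a synthetic annotated EEG recording
#'
#' Background on every channel is 1/f colored noise plus a low-amplitude
#' alpha-range sinusoid (random phase per channel). During each planted
#' seizure interval, the channels named in `config$ictal_spec` additionally
#' carry a rhythmic sinusoid at the stated frequency and amplitude, with a
#' 0.5-s raised-cosine onset/offset ramp. Identical configs (including seed)
#' produce bit-identical output.
#'
#' @param config A [synth_config()].
#' @return An [eeg_recording()] with seizure annotations.
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- as.integer(round(config$duration * config$fs))
  fs <- config$fs
  durations <- config$seizure_duration +
    stats::runif(config$n_seizures, -1, 1) * config$seizure_jitter
  seizures <- place_seizures(durations, config$duration, config$min_gap)

  data <- matrix(0, nrow = config$n_channels, ncol = n)
  tt <- (seq_len(n) - 1) / fs
  bg <- config$background
  for (ch in seq_len(config$n_channels)) {
    phase <- stats::runif(1, 0, 2 * pi)
    data[ch, ] <- colored_noise(n, bg$noise_sd) +
      bg$alpha_amp * sin(2 * pi * bg$alpha_hz * tt + phase)
  }

  if (nrow(seizures) > 0 && nrow(config$ictal_spec) > 0) {
    ramp_s <- 0.5
    for (si in seq_len(nrow(seizures))) {
      i0 <- floor(seizures$start_s[si] * fs) + 1
      i1 <- min(n, ceiling(seizures$end_s[si] * fs))
      idx <- i0:i1
      m <- length(idx)
      env <- rep(1, m)
      nr <- min(m %/% 2, round(ramp_s * fs))
      if (nr > 0) {
        r <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
        env[seq_len(nr)] <- r
        env[m + 1 - seq_len(nr)] <- rev(r)
      }
      for (k in seq_len(nrow(config$ictal_spec))) {
        spec <- config$ictal_spec[k, ]
        phase <- stats::runif(1, 0, 2 * pi)
        data[spec$channel, idx] <- data[spec$channel, idx] +
          spec$gain * env * sin(2 * pi * spec$freq_hz * tt[idx] + phase)
      }
    }
  }
  eeg_recording(data, fs, config$channel_names, seizures)
}

#' Feature names expected to be discriminative for a synthetic config
#'
#' Amplitude-sensitive metrics on the planted channel/band combinations, in
#' the `"band_channel_metric"` naming used by the feature matrix. Because the
#' complete 0.5-30 Hz band contains every planted rhythm, complete-band names
#' are included alongside the specific band.
#'
#' @param config A [synth_config()].
#' @param feature_set `"fs1"` or `"fs2"`.
#' @return Character vector of feature names (empty if nothing planted).
#' @export
ground_truth_features <- function(config, feature_set = c("fs1", "fs2")) {
  feature_set <- match.arg(feature_set)
  spec <- config$ictal_spec
  if (is.null(spec) || nrow(spec) == 0) return(character(0))
  metrics <- switch(feature_set,
    fs1 = c("var", "rms", "range"),
    fs2 = c("min", "iqr", "mad", "sd")
  )
  out <- character(0)
  for (k in seq_len(nrow(spec))) {
    ch <- config$channel_names[spec$channel[k]]
    for (b in unique(c(spec$band[k], "complete"))) {
      out <- c(out, paste(b, ch, metrics, sep = "_"))
    }
  }
  unique(out)
}
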