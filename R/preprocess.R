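#' Preprocessing configuration
#'
#' Filtering, epoching and rebalancing settings for continuous EEG.
#'
#' @param highpass_hz High-pass cutoff in Hz (default 0.5).
#' @param highpass_order Butterworth order of the high-pass (default 2).
#' @param notch_hz Power-line frequency to remove, 50 or 60 Hz.
#' @param notch_q Quality factor of the IIR notch (default 30).
#' @param bands Named list of `(low, high)` Hz pairs; defaults to the
#'   complete 0.5-30 Hz band plus delta, theta, alpha and beta.
#' @param band_filter_order Butterworth order of each band-pass (default 2).
#' @param window_s Epoch length in seconds (default 2).
#' @param ictal_overlap Fractional overlap of consecutive ictal epochs
#'   (default 0.5, i.e. a 1-s stride for 2-s windows).
#' @param target_ratio Maximum non-ictal:ictal epoch ratio kept after
#'   rebalancing (default 9).
#' @param seed Seed for the rebalancing subsample.
#' @return A validated `preprocess_config` list.
#' @export
preprocess_config <- function(highpass_hz = 0.5, highpass_order = 2,
                              notch_hz = 60, notch_q = 30,
                              bands = band_limits(),
                              band_filter_order = 2,
                              window_s = 2, ictal_overlap = 0.5,
                              target_ratio = 9, seed = 1L) {
  stopifnot(highpass_hz > 0, highpass_order >= 1, notch_hz > 0,
            window_s > 0, ictal_overlap > 0, ictal_overlap < 1,
            target_ratio >= 1)
  for (b in bands) stopifnot(length(b) == 2, b[1] > 0, b[2] > b[1])
  structure(list(highpass_hz = highpass_hz, highpass_order = highpass_order,
                 notch_hz = notch_hz, notch_q = notch_q, bands = bands,
                 band_filter_order = band_filter_order, window_s = window_s,
                 ictal_overlap = ictal_overlap, target_ratio = target_ratio,
                 seed = as.integer(seed)),
            class = "preprocess_config")
}

#' Default longitudinal bipolar montage (18 derivations)
#'
#' The standard 10-20 "double banana": four left and right temporal/parasagittal
#' chains plus the midline pair.
#'
#' @return Data frame with `anode` and `cathode` electrode names.
#' @export
default_montage <- function() {
  labs <- default_bipolar_labels(18)
  parts <- strsplit(labs, "-", fixed = TRUE)
  data.frame(anode = vapply(parts, `[`, "", 1),
             cathode = vapply(parts, `[`, "", 2))
}

#' Convert a monopolar recording to a bipolar montage
#'
#' Each output channel is `anode - cathode`; channel names become `"A-C"`.
#'
#' @param rec An [eeg_recording()] with monopolar electrode channel names.
#' @param montage Data frame with `anode`/`cathode` columns; defaults to the
#'   18-derivation double banana.
#' @return A bipolar [eeg_recording()].
#' @export
to_bipolar <- function(rec, montage = default_montage()) {
  stopifnot(inherits(rec, "eeg_recording"))
  electrodes <- toupper(rec$channel_names)
  need <- toupper(unique(c(montage$anode, montage$cathode)))
  missing <- setdiff(need, electrodes)
  if (length(missing) > 0) {
    stop("montage references electrodes absent from the recording: ",
         paste(missing, collapse = ", "))
  }
  out <- matrix(0, nrow = nrow(montage), ncol = ncol(rec$data))
  for (i in seq_len(nrow(montage))) {
    a <- match(toupper(montage$anode[i]), electrodes)
    c_ <- match(toupper(montage$cathode[i]), electrodes)
    out[i, ] <- rec$data[a, ] - rec$data[c_, ]
  }
  eeg_recording(out, rec$fs,
                paste(toupper(montage$anode), toupper(montage$cathode),
                      sep = "-"),
                rec$seizures)
}

# Zero-phase (forward-backward) IIR filtering with odd-reflection edge
# padding, so step-like edges and DC offsets do not leave boundary
# transients in the output.
zero_phase_filter <- function(b, a, x, padlen = 3072L) {
  n <- length(x)
  padlen <- min(n - 1L, padlen)
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - padlen)]
  xp <- c(pre, x, post)
  y <- signal::filter(b, a, xp)
  y <- rev(as.numeric(signal::filter(b, a, rev(as.numeric(y)))))
  y[(padlen + 1):(padlen + n)]
}

# Second-order IIR notch (biquad) at f0 with quality factor q, from the
# standard audio-EQ closed form; returned as (b, a) coefficient vectors.
notch_coefficients <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' High-pass and notch filter a recording
#'
#' Per channel: a Butterworth high-pass removes drift below the cutoff, then
#' an IIR notch removes the power-line component. Both are applied zero-phase
#' (forward-backward), which keeps epoch/annotation alignment exact; the
#' effective attenuation is the squared magnitude response.
#'
#' @param rec An [eeg_recording()].
#' @param config A [preprocess_config()].
#' @return The filtered [eeg_recording()], same length.
#' @export
filter_recording <- function(rec, config) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs <= 2 * config$notch_hz) {
    stop("sampling rate too low for the requested notch frequency")
  }
  if (config$highpass_hz >= rec$fs / 2) {
    stop("high-pass cutoff at or above Nyquist")
  }
  hp <- signal::butter(config$highpass_order,
                       config$highpass_hz / (rec$fs / 2), type = "high")
  nc <- notch_coefficients(config$notch_hz, rec$fs, config$notch_q)
  out <- rec$data
  for (ch in seq_len(nrow(out))) {
    x <- zero_phase_filter(hp$b, hp$a, out[ch, ])
    out[ch, ] <- zero_phase_filter(nc$b, nc$a, x)
  }
  eeg_recording(out, rec$fs, rec$channel_names, rec$seizures)
}

#' Epoch set container
#'
#' @param epochs n x channels x samples array, or a named list of such arrays
#'   (one per band) for band-decomposed sets.
#' @param labels Integer vector, 1 = ictal, 0 = non-ictal.
#' @param channel_names Channel labels.
#' @param fs Sampling rate in Hz.
#' @param band_names Band names if decomposed, else `NULL`.
#' @return An `epoch_set` object.
#' @export
epoch_set <- function(epochs, labels, channel_names, fs, band_names = NULL) {
  if (is.list(epochs)) {
    dims <- unique(lapply(epochs, dim))
    stopifnot(length(dims) == 1)
    n <- dims[[1]][1]
    band_names <- names(epochs)
  } else {
    n <- dim(epochs)[1]
  }
  stopifnot(length(labels) == n)
  structure(list(epochs = epochs, labels = as.integer(labels),
                 channel_names = channel_names, fs = fs,
                 band_names = band_names),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("<epoch_set> %d epochs (%d ictal), %d channels @ %g Hz%s\n",
              n, sum(x$labels), length(x$channel_names), x$fs,
              if (!is.null(x$band_names))
                paste0(", bands: ", paste(x$band_names, collapse = "/"))
              else ""))
  invisible(x)
}

#' Cut a recording into labeled fixed-length epochs
#'
#' Ictal portions are cut into `window_s` epochs with the configured overlap
#' (a 1-s stride for the default 2-s windows at 50% overlap), starting at each
#' annotated seizure onset. Non-ictal portions are cut into non-overlapping
#' epochs fully outside every seizure interval, so no epoch mixes classes;
#' partial windows at segment boundaries are discarded.
#'
#' @param rec An [eeg_recording()].
#' @param config A [preprocess_config()].
#' @return An [epoch_set()] (not yet band-decomposed).
#' @export
segment_epochs <- function(rec, config) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  w <- as.integer(round(config$window_s * fs))
  n <- ncol(rec$data)
  dur <- n / fs
  if (dur < config$window_s) stop("recording shorter than one window")
  stride_ictal <- as.integer(round(w * (1 - config$ictal_overlap)))

  starts <- integer(0)
  labels <- integer(0)
  sz <- rec$seizures
  # ictal epochs: stride within each annotated interval
  if (nrow(sz) > 0) {
    for (i in seq_len(nrow(sz))) {
      s0 <- as.integer(round(sz$start_s[i] * fs))
      s1 <- as.integer(round(sz$end_s[i] * fs))
      if (s1 - s0 >= w) {
        st <- seq(s0, s1 - w, by = stride_ictal)
        starts <- c(starts, st)
        labels <- c(labels, rep(1L, length(st)))
      }
    }
  }
  # non-ictal epochs: tile the gaps between seizures
  gaps_start <- c(0, if (nrow(sz) > 0) as.integer(round(sz$end_s * fs)))
  gaps_end <- c(if (nrow(sz) > 0) as.integer(round(sz$start_s * fs)), n)
  for (g in seq_along(gaps_start)) {
    if (gaps_end[g] - gaps_start[g] >= w) {
      st <- seq(gaps_start[g], gaps_end[g] - w, by = w)
      starts <- c(starts, st)
      labels <- c(labels, rep(0L, length(st)))
    }
  }
  o <- order(starts)
  starts <- starts[o]; labels <- labels[o]
  arr <- array(0, dim = c(length(starts), nrow(rec$data), w))
  for (i in seq_along(starts)) {
    arr[i, , ] <- rec$data[, (starts[i] + 1):(starts[i] + w), drop = FALSE]
  }
  epoch_set(arr, labels, rec$channel_names, fs)
}

#' Subsample non-ictal epochs to restore the target class ratio
#'
#' Keeps every ictal epoch and draws a uniform seeded subsample of non-ictal
#' epochs of size `min(available, target_ratio x ictal count)`. No epoch is
#' duplicated.
#'
#' @param es An [epoch_set()].
#' @param config A [preprocess_config()] (uses `target_ratio` and `seed`).
#' @return The rebalanced [epoch_set()].
#' @export
rebalance <- function(es, config) {
  stopifnot(inherits(es, "epoch_set"))
  if (sum(es$labels == 1L) == 0) {
    stop("cannot rebalance: no ictal epochs present")
  }
  ictal <- which(es$labels == 1L)
  noni <- which(es$labels == 0L)
  keep_n <- min(length(noni), config$target_ratio * length(ictal))
  set.seed(config$seed)
  keep <- sort(c(ictal, sample(noni, keep_n)))
  subset_epochs(es, keep)
}

subset_epochs <- function(es, idx) {
  if (is.list(es$epochs)) {
    eps <- lapply(es$epochs, function(a) a[idx, , , drop = FALSE])
  } else {
    eps <- es$epochs[idx, , , drop = FALSE]
  }
  epoch_set(eps, es$labels[idx], es$channel_names, es$fs, es$band_names)
}

#' Decompose epochs into frequency sub-bands
#'
#' Applies a zero-phase Butterworth band-pass per configured band to every
#' epoch and channel. The complete 0.5-30 Hz copy goes through the same
#' band-pass machinery as the four sub-bands, for uniform treatment.
#'
#' @param es An [epoch_set()] (not yet decomposed).
#' @param config A [preprocess_config()].
#' @return An [epoch_set()] whose `epochs` field is a named per-band list.
#' @export
band_decompose <- function(es, config) {
  stopifnot(inherits(es, "epoch_set"), !is.list(es$epochs))
  nyq <- es$fs / 2
  filters <- lapply(config$bands, function(b) {
    if (b[2] >= nyq) stop("band edge at or above Nyquist: ", b[2], " Hz")
    signal::butter(config$band_filter_order, c(b[1], b[2]) / nyq,
                   type = "pass")
  })
  dims <- dim(es$epochs)
  out <- lapply(filters, function(f) {
    a <- array(0, dim = dims)
    for (ch in seq_len(dims[2])) {
      for (i in seq_len(dims[1])) {
        a[i, ch, ] <- zero_phase_filter(f$b, f$a, es$epochs[i, ch, ])
      }
    }
    a
  })
  names(out) <- names(config$bands)
  epoch_set(out, es$labels, es$channel_names, es$fs, names(out))
}
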