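make_monopolar <- function(electrodes, fs = 256, dur = 4, seed = 1) {
  set.seed(seed)
  n <- dur * fs
  eeg_recording(matrix(rnorm(length(electrodes) * n), length(electrodes), n),
                fs, electrodes)
}

test_that("bipolar conversion subtracts electrode pairs by name", {
  rec <- make_monopolar(c("FP1", "F3"))
  rec$data[2, ] <- rec$data[1, ]  # identical electrodes
  bip <- to_bipolar(rec, data.frame(anode = "FP1", cathode = "F3"))
  expect_equal(unname(bip$data[1, ]), rep(0, ncol(rec$data)))
  expect_equal(bip$channel_names, "FP1-F3")

  electrodes_1020 <- c("FP1", "FP2", "F3", "F4", "C3", "C4", "P3", "P4",
                       "O1", "O2", "F7", "F8", "T7", "T8", "P7", "P8",
                       "FZ", "CZ", "PZ")
  full <- make_monopolar(electrodes_1020)
  bip <- to_bipolar(full)
  expect_equal(nrow(bip$data), 18)

  missing_pz <- make_monopolar(setdiff(electrodes_1020, "PZ"))
  expect_error(to_bipolar(missing_pz), "PZ")
})

test_that("high-pass plus notch remove DC and line noise, keep the passband", {
  fs <- 256
  tt <- seq(0, 8 - 1 / fs, by = 1 / fs)
  pc <- preprocess_config(notch_hz = 60)

  const <- eeg_recording(matrix(5, 1, length(tt)), fs, "A-B")
  out <- filter_recording(const, pc)
  expect_lt(max(abs(out$data)), 1e-6)

  line <- eeg_recording(matrix(sin(2 * pi * 60 * tt), 1, length(tt)),
                        fs, "A-B")
  filtered <- filter_recording(line, pc)
  core <- seq(fs, length(tt) - fs)  # ignore filter edge transients
  expect_lt(mean(filtered$data[1, core]^2) / mean(line$data[1, core]^2),
            0.01)

  alpha <- eeg_recording(matrix(sin(2 * pi * 10 * tt), 1, length(tt)),
                         fs, "A-B")
  kept <- filter_recording(alpha, pc)
  amp_ratio <- sqrt(mean(kept$data[1, core]^2) / mean(alpha$data[1, core]^2))
  expect_gt(amp_ratio, 0.95)
  expect_lt(amp_ratio, 1.05)
})

test_that("zero-phase filtering keeps a symmetric pulse symmetric", {
  fs <- 256
  n <- 4 * fs
  x <- exp(-((seq_len(n) - n / 2)^2) / (2 * 20^2))  # centered Gaussian pulse
  rec <- eeg_recording(matrix(x, 1, n), fs, "A-B")
  out <- filter_recording(rec, preprocess_config())$data[1, ]
  # symmetry about the pulse center n/2: out[c + d] == out[c - d]
  core <- seq_len(n / 4)
  left <- out[n / 2 - core]
  right <- out[n / 2 + core]
  expect_lt(max(abs(left - right)), 1e-4 * max(abs(out)))
})

test_that("band decomposition isolates energy into the right bands", {
  fs <- 256
  pc <- preprocess_config()
  tt <- seq(0, 2 - 1 / fs, by = 1 / fs)
  mk_es <- function(f) {
    arr <- array(0, dim = c(1, 1, length(tt)))
    arr[1, 1, ] <- sin(2 * pi * f * tt)
    epoch_set(arr, 0L, "A-B", fs)
  }
  dec10 <- band_decompose(mk_es(10), pc)
  v_in <- var(sin(2 * pi * 10 * tt))
  expect_gt(var(dec10$epochs$alpha[1, 1, ]) / v_in, 0.8)
  expect_lt(var(dec10$epochs$delta[1, 1, ]) / v_in, 0.1)

  dec2 <- band_decompose(mk_es(2), pc)
  vars <- vapply(c("delta", "theta", "alpha", "beta"),
                 function(b) var(dec2$epochs[[b]][1, 1, ]), numeric(1))
  expect_equal(names(which.max(vars)), "delta")

  # shape conservation across bands
  es <- small_epochs()
  dims <- unique(lapply(es$epochs, dim))
  expect_length(dims, 1)
  expect_equal(length(es$band_names), 5)

  bad <- preprocess_config(bands = list(hf = c(100, 200)))
  expect_error(band_decompose(mk_es(10), bad), "Nyquist")
})

test_that("segmentation strides ictal windows and tiles the background", {
  fs <- 256
  pc <- preprocess_config()
  rec <- eeg_recording(matrix(rnorm(10 * fs), 1, 10 * fs), fs, "A-B",
                       data.frame(start_s = 4, end_s = 8))
  es <- segment_epochs(rec, pc)
  expect_equal(sum(es$labels), 3)  # ictal starts at 4, 5, 6 s

  none <- eeg_recording(matrix(rnorm(60 * fs), 1, 60 * fs), fs, "A-B")
  es0 <- segment_epochs(none, pc)
  expect_equal(sum(es0$labels), 0)
  expect_equal(length(es0$labels), 30)
})

test_that("rebalancing keeps every ictal epoch and caps the ratio", {
  fs <- 64
  w <- 2 * fs
  n_epochs <- 210
  arr <- array(rnorm(n_epochs * 1 * w), dim = c(n_epochs, 1, w))
  labels <- c(rep(1L, 10), rep(0L, 200))
  es <- epoch_set(arr, labels, "A-B", fs)
  pc <- preprocess_config(seed = 5)
  out <- rebalance(es, pc)
  expect_equal(sum(out$labels), 10)
  expect_equal(sum(out$labels == 0), 90)

  # no duplication: every kept epoch matches a distinct original epoch
  kept_keys <- apply(out$epochs[, 1, 1:5], 1, paste, collapse = ",")
  orig_keys <- apply(arr[, 1, 1:5], 1, paste, collapse = ",")
  expect_true(all(kept_keys %in% orig_keys))
  expect_false(anyDuplicated(kept_keys) > 0)

  under <- epoch_set(arr[1:60, , , drop = FALSE],
                     c(rep(1L, 10), rep(0L, 50)), "A-B", fs)
  expect_equal(length(rebalance(under, pc)$labels), 60)

  out2 <- rebalance(es, pc)
  expect_identical(out$labels, out2$labels)
  expect_identical(out$epochs, out2$epochs)

  no_ictal <- epoch_set(arr[1:20, , , drop = FALSE], rep(0L, 20), "A-B", fs)
  expect_error(rebalance(no_ictal, pc), "ictal")
})
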