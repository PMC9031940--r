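test_that("generated recordings have the configured shape and annotations", {
  cfg <- synth_config(n_channels = 4, duration = 60, n_seizures = 1,
                      seizure_duration = 10, seizure_jitter = 2, seed = 3)
  rec <- generate_recording(cfg)
  expect_equal(dim(rec$data), c(4, 60 * 256))
  expect_equal(rec$channel_names, default_bipolar_labels(4))
  expect_equal(nrow(rec$seizures), 1)
  expect_true(rec$seizures$start_s >= 0 && rec$seizures$end_s <= 60)

  quiet <- generate_recording(synth_config(n_channels = 2, duration = 30,
                                           n_seizures = 0, seed = 3))
  expect_equal(nrow(quiet$seizures), 0)
  es <- segment_epochs(quiet, preprocess_config())
  expect_equal(sum(es$labels), 0)
})

test_that("identical seeds give bit-identical recordings", {
  cfg <- synth_config(n_channels = 3, duration = 40, n_seizures = 2,
                      seizure_duration = 6, seizure_jitter = 1, seed = 99)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$data, b$data)
  expect_identical(a$seizures, b$seizures)
})

test_that("infeasible seizure placement is rejected", {
  cfg <- synth_config(n_channels = 2, duration = 30, n_seizures = 4,
                      seizure_duration = 10, seizure_jitter = 0, seed = 1)
  expect_error(generate_recording(cfg), "infeasible")
})

test_that("raising a planted gain widens the ictal/background RMS contrast", {
  rms_contrast <- function(gain, seed) {
    cfg <- synth_config(
      n_channels = 2, duration = 240, n_seizures = 2,
      seizure_duration = 15, seizure_jitter = 2,
      ictal_spec = data.frame(channel = 1L, band = "delta",
                              gain = gain, freq_hz = 3),
      seed = seed
    )
    pc <- preprocess_config()
    es <- segment_epochs(generate_recording(cfg), pc)
    esb <- band_decompose(es, pc)
    arr <- esb$epochs$delta
    rms <- sqrt(apply(arr[, 1, , drop = TRUE]^2, 1, mean))
    mean(rms[es$labels == 1]) - mean(rms[es$labels == 0])
  }
  for (seed in c(5, 6)) {
    expect_gt(rms_contrast(60, seed), rms_contrast(15, seed))
    expect_gt(rms_contrast(15, seed), 0)
  }
})

test_that("ground-truth feature names follow the planted spec", {
  cfg <- synth_config(
    n_channels = 4, duration = 60, n_seizures = 1, seizure_duration = 10,
    seizure_jitter = 1,
    ictal_spec = data.frame(channel = 1L, band = "delta",
                            gain = 40, freq_hz = 4),
    seed = 1
  )
  gt <- ground_truth_features(cfg, "fs1")
  expect_true(paste0("delta_", cfg$channel_names[1], "_rms") %in% gt)
  expect_true(all(grepl(cfg$channel_names[1], gt, fixed = TRUE)))

  none <- synth_config(n_channels = 4, duration = 60, n_seizures = 0,
                       ictal_spec = data.frame(channel = integer(0),
                                               band = character(0),
                                               gain = numeric(0),
                                               freq_hz = numeric(0)),
                       seed = 1)
  expect_length(ground_truth_features(none), 0)

  alpha2 <- synth_config(
    n_channels = 4, duration = 60, n_seizures = 1, seizure_duration = 10,
    seizure_jitter = 1,
    ictal_spec = data.frame(channel = 3L, band = "alpha",
                            gain = 40, freq_hz = 10),
    seed = 1
  )
  gt2 <- ground_truth_features(alpha2, "fs2")
  expect_false(any(grepl(alpha2$channel_names[4], gt2, fixed = TRUE)))
  expect_true(any(grepl("^alpha_", gt2)))
})

test_that("recordings round-trip through the delimited format with sidecar", {
  cfg <- synth_config(n_channels = 3, duration = 10, n_seizures = 1,
                      seizure_duration = 4, seizure_jitter = 0.5,
                      min_gap = 2, seed = 8)
  rec <- generate_recording(cfg)
  path <- file.path(withr::local_tempdir(), "rec.tsv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$channel_names, rec$channel_names)
  expect_equal(back$data, rec$data, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$seizures$start_s, rec$seizures$start_s, tolerance = 1e-9)

  # missing sidecar: empty seizure list plus a warning
  file.remove(paste0(path, ".annotations.tsv"))
  expect_warning(noann <- read_recording(path), "sidecar")
  expect_equal(nrow(noann$seizures), 0)

  # truncated header is a parse error
  bad <- file.path(withr::local_tempdir(), "bad.tsv")
  writeLines("# fs\t256", bad)
  expect_error(read_recording(bad), "header")

  expect_error(load_external_recording(path, "edf"), "EDF")
})
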