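test_that("amplitude statistics match hand-computed values", {
  s <- amplitude_stats(c(1, -1, 1, -1))
  expect_equal(s$zero_crossings, 3)
  expect_equal(s$range, 2)
  expect_equal(s$mean, 0)

  const <- amplitude_stats(c(5, 5, 5, 5))
  expect_equal(const$variance, 0)
  expect_equal(const$rms, 5)
  expect_equal(const$mad, 0)
  expect_equal(const$iqr, 0)
  expect_equal(const$skewness, 0)
  expect_equal(const$kurtosis, 0)

  ramp <- amplitude_stats(c(1, 2, 3, 4, 5))
  expect_equal(ramp$iqr, 2)
  expect_equal(ramp$mad, 1)
  expect_equal(ramp$minimum, 1)

  # exact zero samples inherit the previous sign: no double counting
  expect_equal(amplitude_stats(c(1, 0, -1, 0, 1))$zero_crossings, 2)
})

test_that("spectral metrics locate sinusoid frequencies within resolution", {
  fs <- 256
  tt <- seq(0, 2 - 1 / fs, by = 1 / fs)
  pure <- spectral_metrics(sin(2 * pi * 10 * tt), fs)
  expect_equal(pure$peak_frequency, 10, tolerance = 0.51)
  expect_equal(pure$median_frequency, 10, tolerance = 0.51)

  mix <- spectral_metrics(sin(2 * pi * 5 * tt) + sin(2 * pi * 15 * tt), fs)
  expect_gt(mix$median_frequency, 5)
  expect_lt(mix$median_frequency, 15)

  silent <- spectral_metrics(rep(0, 512), fs)
  expect_equal(silent$median_frequency, 0)
  expect_equal(silent$peak_frequency, 0)
})

test_that("Hjorth mobility matches the discrete sinusoid closed form", {
  fs <- 256
  tt <- seq(0, 4 - 1 / fs, by = 1 / fs)
  for (f in c(2, 5, 10, 20)) {
    h <- hjorth_params(sin(2 * pi * f * tt))
    expect_equal(h$mobility, 2 * sin(pi * f / fs), tolerance = 1e-3)
  }
  expect_equal(hjorth_params(rep(3, 100)), list(mobility = 0, complexity = 0))
  set.seed(4)
  complexities <- replicate(5, hjorth_params(rnorm(512))$complexity)
  expect_true(all(complexities > 1))
})

test_that("sample entropy handles degenerate and periodic signals", {
  expect_equal(sample_entropy(rep(2, 50)), 0)
  expect_equal(sample_entropy(rep(c(1, 2), 50)), 0, tolerance = 1e-9)
  set.seed(9)
  vals <- replicate(5, sample_entropy(rnorm(200)))
  expect_true(all(vals >= 0))
  expect_error(sample_entropy(c(1, 2, 3)), "short")
})

test_that("feature columns follow the band/channel/metric layout", {
  fs <- 64
  mk <- function(n_ch, bands = c("complete", "delta", "theta", "alpha",
                                 "beta"),
                 n_ep = 4, w = 64) {
    set.seed(1)
    eps <- lapply(bands, function(b) {
      array(rnorm(n_ep * n_ch * w), dim = c(n_ep, n_ch, w))
    })
    names(eps) <- bands
    epoch_set(eps, rep(0:1, length.out = n_ep),
              default_bipolar_labels(n_ch), fs)
  }
  one <- extract_features(mk(1, bands = "alpha"), feature_config("fs1"))
  expect_equal(ncol(one$values), 8)
  expect_true(all(startsWith(colnames(one$values), "alpha_")))

  two <- extract_features(mk(2), feature_config("fs2"))
  expect_equal(ncol(two$values), 5 * 2 * 8)
  # band-major, then channel, then metric
  expect_equal(colnames(two$values)[1:3],
               paste("complete", default_bipolar_labels(1),
                     c("min", "complexity", "mobility"), sep = "_"))
  expect_equal(colnames(two$values)[9],
               paste("complete", default_bipolar_labels(2)[2], "min",
                     sep = "_"))
})

test_that("scaling an epoch scales amplitude metrics and fixes shape metrics", {
  set.seed(12)
  x <- rnorm(256)
  c_ <- 3.7
  a1 <- amplitude_stats(x)
  a2 <- amplitude_stats(c_ * x)
  for (nm in c("rms", "range", "sd", "iqr", "mad", "minimum")) {
    expect_equal(a2[[nm]], c_ * a1[[nm]], tolerance = 1e-10)
  }
  expect_equal(a2$variance, c_^2 * a1$variance, tolerance = 1e-10)
  for (nm in c("skewness", "kurtosis", "zero_crossings")) {
    expect_equal(a2[[nm]], a1[[nm]], tolerance = 1e-10)
  }
  expect_equal(a2$mean, c_ * a1$mean, tolerance = 1e-10)
  h1 <- hjorth_params(x); h2 <- hjorth_params(c_ * x)
  expect_equal(h2$mobility, h1$mobility, tolerance = 1e-10)
  expect_equal(h2$complexity, h1$complexity, tolerance = 1e-10)
  s1 <- spectral_metrics(x, 256); s2 <- spectral_metrics(c_ * x, 256)
  expect_equal(s1, s2)
  expect_equal(sample_entropy(c_ * x), sample_entropy(x), tolerance = 1e-9)
})

test_that("correlation pruning drops later duplicates and is idempotent", {
  set.seed(3)
  n <- 1000
  base <- matrix(rnorm(n * 3), n, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  dup <- cbind(base, a_copy = base[, "a"])
  fm <- feature_matrix(dup, rep(0:1, length.out = n))
  pr <- prune_correlated(fm)
  expect_equal(pr$dropped, "a_copy")
  expect_equal(colnames(pr$fm$values), c("a", "b", "c"))

  # independent noise columns survive
  expect_length(prune_correlated(feature_matrix(
    base, rep(0:1, length.out = n)))$dropped, 0)

  tri <- cbind(base[, 1, drop = FALSE],
               x2 = base[, 1], x3 = base[, 1], b = base[, 2])
  pr3 <- prune_correlated(feature_matrix(tri, rep(0:1, length.out = n)))
  expect_equal(pr3$dropped, c("x2", "x3"))

  # anti-correlated duplicates are caught by the absolute-value rule
  anti <- cbind(base, neg_a = -base[, "a"])
  expect_equal(prune_correlated(feature_matrix(
    anti, rep(0:1, length.out = n)))$dropped, "neg_a")

  # idempotence
  again <- prune_correlated(pr$fm)
  expect_length(again$dropped, 0)
  expect_equal(again$fm$values, pr$fm$values)

  # constant columns are retained and audited
  zv <- cbind(base, flat = rep(1, n))
  przv <- prune_correlated(feature_matrix(zv, rep(0:1, length.out = n)))
  expect_true("flat" %in% colnames(przv$fm$values))
  expect_equal(przv$zero_variance, "flat")
})

test_that("feature matrices round-trip through CSV", {
  fm <- small_fm()
  path <- file.path(withr::local_tempdir(), "fm.csv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(colnames(back$values), colnames(fm$values))
  expect_equal(back$labels, fm$labels)
  expect_equal(back$values, fm$values, tolerance = 1e-8)
})
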