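# Shared fixtures, built in code and memoized so heavy objects are computed
# once per test run.

.fixture_env <- new.env(parent = emptyenv())

memoize <- function(name, compute) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, compute(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Small annotated recording with one strongly discriminative channel/band.
small_synth_config <- function(seed = 42) {
  synth_config(
    n_channels = 4, duration = 300, n_seizures = 3,
    seizure_duration = 15, seizure_jitter = 3,
    ictal_spec = data.frame(channel = 1L, band = "delta",
                            gain = 60, freq_hz = 3),
    seed = seed
  )
}

# Band-decomposed, rebalanced epochs of the small recording.
small_epochs <- function() {
  memoize("small_epochs", function() {
    pc <- preprocess_config(seed = 7)
    rec <- generate_recording(small_synth_config())
    es <- rebalance(segment_epochs(filter_recording(rec, pc), pc), pc)
    band_decompose(es, pc)
  })
}

# Pruned fs1 feature matrix of the small recording.
small_fm <- function() {
  memoize("small_fm", function() {
    fm <- extract_features(small_epochs(), feature_config("fs1"))
    prune_correlated(fm)$fm
  })
}

# Toy tabular problem: first feature separates the classes, the rest are
# noise; scaled to [0, 1].
toy_separable <- function(n = 120, p = 6, gap = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(stats::rnorm(n * p), n, p)
  X[, 1] <- X[, 1] + gap * y
  colnames(X) <- paste0("f", seq_len(p))
  list(X = minmax_scale(X)$train, y = y)
}

# Brute-force Shapley values of a background-imputed value function,
# independent of the kernel-SHAP solver.
brute_force_shapley <- function(model, x0, background) {
  M <- length(x0)
  vfun <- function(S) {
    big <- background
    for (j in S) big[, j] <- x0[j]
    colnames(big) <- names(x0)
    mean(predict_classifier(model, big, type = "prob"))
  }
  phi <- numeric(M)
  for (j in seq_len(M)) {
    others <- setdiff(seq_len(M), j)
    for (size in 0:(M - 1)) {
      combs <- if (size == 0) matrix(integer(0), 0, 1) else
        utils::combn(others, size)
      for (c_i in seq_len(ncol(combs))) {
        S <- combs[, c_i]
        w <- factorial(size) * factorial(M - size - 1) / factorial(M)
        phi[j] <- phi[j] + w * (vfun(c(S, j)) - vfun(S))
      }
    }
  }
  phi
}

# Planted-structure study fixture used by the recovery checks: six channels,
# half an hour of signal, two discriminative channel/band combinations, and
# enough background for the 9:1 rebalancing to engage.
recovery_config <- function(seed = 2024) {
  synth_config(
    n_channels = 6, duration = 1800, n_seizures = 5,
    seizure_duration = 20, seizure_jitter = 4,
    ictal_spec = data.frame(channel = c(1L, 3L),
                            band = c("delta", "alpha"),
                            gain = c(45, 35), freq_hz = c(3, 10)),
    seed = seed
  )
}

recovery_artifacts <- function() {
  memoize("recovery_artifacts", function() {
    cfg <- recovery_config()
    pc <- preprocess_config(seed = 11)
    rec <- generate_recording(cfg)
    es <- rebalance(segment_epochs(filter_recording(rec, pc), pc), pc)
    fm <- prune_correlated(extract_features(band_decompose(es, pc),
                                            feature_config("fs1")))$fm
    clf <- classifier_config("RF", seed = 5)
    rks <- compute_rankings(fm, clf, fsm_config(seed = 17))
    gt <- intersect(ground_truth_features(cfg, "fs1"), colnames(fm$values))
    list(cfg = cfg, fm = fm, clf = clf, rankings = rks, gt = gt)
  })
}
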