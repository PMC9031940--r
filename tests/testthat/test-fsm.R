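test_that("rankings sort scores non-increasingly with stable ties", {
  rk <- new_ranking(c(a = 0.2, b = 0.5, c = 0.2, d = -0.9), "toy")
  expect_equal(rk$order, c("d", "b", "a", "c"))  # abs convention; a before c
  expect_true(all(diff(rk$scores[rk$order]) <= 0))
  expect_true(all(rk$scores >= 0))
})

test_that("decision-tree Gini importance concentrates on the splitting feature", {
  d <- toy_separable(n = 200, p = 5, gap = 4, seed = 2)
  rk <- rank_dt_gini(d$X, d$y)
  expect_equal(rk$order[1], "f1")
  expect_equal(sum(rk$scores), 1, tolerance = 1e-9)
  # features the tree never split on score exactly zero
  expect_true(any(rk$scores == 0))
  expect_error(rank_dt_gini(d$X, rep(1, nrow(d$X))), "single class")
})

test_that("linear-SVM weights rank the informative feature first", {
  d <- toy_separable(n = 200, p = 5, gap = 4, seed = 3)
  rk <- rank_svm_weights(d$X, d$y)
  expect_equal(rk$order[1], "f1")
  expect_true(all(rk$scores >= 0))

  # a duplicated informative feature may split its weight, but the pair
  # together still outweighs any noise feature
  X2 <- cbind(d$X, f1_copy = d$X[, "f1"])
  rk2 <- rank_svm_weights(X2, d$y)
  pair <- rk2$scores["f1"] + rk2$scores["f1_copy"]
  expect_gt(pair, max(rk2$scores[c("f2", "f3", "f4", "f5")]))
})

test_that("LIME recovers the dominant coefficient of an analytic model", {
  set.seed(6)
  M <- 5
  X <- matrix(runif(80 * M), 80, M, dimnames = list(NULL, paste0("f", 1:M)))
  y <- as.integer(X[, 1] > 0.5)
  model <- custom_model(function(Z) stats::plogis(3 * (Z[, 1] - 0.5)))
  cfg <- fsm_config(lime = list(n_samples = 500, n_explain = 10), seed = 1)
  rk <- rank_lime(X, y, model, cfg)
  expect_equal(rk$order[1], "f1")

  # a feature the model provably ignores scores near zero
  expect_lt(rk$scores["f3"], 0.05 * max(rk$scores))

  rk2 <- rank_lime(X, y, model, cfg)
  expect_identical(rk$scores, rk2$scores)  # fixed seed, fixed output
})

test_that("kernel SHAP with full enumeration equals brute-force Shapley", {
  set.seed(7)
  M <- 8
  X <- matrix(runif(30 * M), 30, M, dimnames = list(NULL, paste0("f", 1:M)))
  model <- custom_model(function(Z) {
    stats::plogis(2 * Z[, 1] - 1.5 * Z[, 2] + 0.5 * Z[, 3] - 0.2)
  })
  bg <- X[1:6, ]
  x0 <- X[15, ]
  phi <- kernel_shap_explain(model, x0, bg)
  exact <- brute_force_shapley(model, x0, bg)
  expect_lt(max(abs(as.numeric(phi) - exact)), 1e-6)

  # local accuracy: attributions sum to f(x) minus the background mean
  fx <- predict_classifier(model, matrix(x0, 1,
                                         dimnames = list(NULL, names(x0))),
                           type = "prob")
  expect_equal(sum(phi), fx - attr(phi, "phi0"), tolerance = 1e-9)

  # dummy property: ignored features get exactly zero attribution
  expect_lt(max(abs(as.numeric(phi)[4:8])), 1e-9)
})

test_that("permutation importance singles out the planted feature", {
  d <- toy_separable(n = 300, p = 5, gap = 3, seed = 8)
  half <- seq_len(150)
  cfg <- fsm_config(seed = 4)
  rk <- rank_erf_permutation(d$X[half, ], d$y[half], cfg,
                             d$X[-half, ], d$y[-half])
  expect_equal(rk$order[1], "f1")
  expect_gt(rk$scores["f1"], max(rk$scores[-1]))
  # pure-noise features move the holdout error by < 2 percentage points
  expect_lt(max(rk$scores[c("f2", "f3", "f4", "f5")]), 0.02)

  rk2 <- rank_erf_permutation(d$X[half, ], d$y[half], cfg,
                              d$X[-half, ], d$y[-half])
  expect_identical(rk$scores, rk2$scores)
  expect_error(rank_erf_permutation(d$X[half, ], d$y[half], cfg,
                                    d$X[-half, ], rep(1, 150)),
               "single class")
})

test_that("reciprocal rank fusion follows the harmonic-combination rule", {
  feats <- paste0("f", 1:4)
  mk <- function(order) {
    sc <- stats::setNames(rev(seq_along(order)), order)
    new_ranking(sc[feats], "m")
  }
  five <- replicate(5, mk(feats), simplify = FALSE)
  fused <- reciprocal_rank_fusion(five)
  # ranked first by all five lists: r(f) = 1/5, stored score = 5
  expect_equal(attr(fused, "fused_value")[["f1"]], 0.2)
  expect_equal(fused$scores[["f1"]], 5)
  expect_equal(fused$order, feats)

  # fusing identical rankings preserves their order
  two <- list(mk(c("f3", "f1", "f4", "f2")), mk(c("f3", "f1", "f4", "f2")))
  expect_equal(reciprocal_rank_fusion(two)$order, c("f3", "f1", "f4", "f2"))

  # ranked 2nd and 3rd: r(f) = 1 / (1/2 + 1/3) = 1.2
  pair <- list(mk(c("f2", "f1", "f3", "f4")), mk(c("f2", "f3", "f1", "f4")))
  expect_equal(attr(reciprocal_rank_fusion(pair), "fused_value")[["f1"]],
               1.2)

  bad <- list(mk(feats), new_ranking(c(g1 = 1, g2 = 2, g3 = 3, g4 = 4), "m"))
  expect_error(reciprocal_rank_fusion(bad), "different feature sets")
})

test_that("instance aggregation is abs-then-mean", {
  m <- matrix(c(1, -1, 0, 0.5), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(aggregate_instance_importance(m), c(a = 1, b = 0.25))
  single <- matrix(c(-2, 3), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(aggregate_instance_importance(single), c(a = 2, b = 3))
  zeros <- matrix(0, 3, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(aggregate_instance_importance(zeros), c(a = 0, b = 0))
})

test_that("rankings persist to CSV with a config sidecar", {
  rk <- new_ranking(c(a = 0.1, b = 0.7, c = 0.3), "toy")
  path <- file.path(withr::local_tempdir(), "rk.csv")
  write_ranking(rk, path)
  back <- read.csv(path)
  expect_equal(back$feature_name, c("b", "c", "a"))
  expect_equal(back$rank, 1:3)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$method, "toy")
})
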