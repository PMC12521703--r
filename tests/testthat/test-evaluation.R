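test_that("mae matches hand computation", {
  expect_equal(mae(matrix(1:4, 2), matrix(1:4, 2)), 0)
  expect_equal(mae(matrix(1:4, 2) + 1, matrix(1:4, 2)), 1)
  p <- matrix(c(0.5, 2, -1, 3, 0, 1), 3, 2)
  t <- matrix(c(1, 1, -2, 2.5, 1, 0), 3, 2)
  expect_equal(mae(p, t), sum(abs(p - t)) / 6)      # explicit sum oracle
  expect_error(mae(matrix(0, 2, 2), matrix(0, 3, 2)),
               class = "retentime_dimension_error")
})

test_that("top-K recall handles exhaustive, perfect and per-patient inputs", {
  rk <- list(c(3, 1, 2), c(2, 3, 1))
  expect_equal(top_k_recall(rk, c(2, 1), K = 3), 100)   # K >= vocab
  expect_equal(top_k_recall(list(c(5, 1), c(7, 2)), c(5, 7), K = 1), 100)
  # per-patient averaging: patient A hits 1/2, patient B 1/1 -> mean 75%
  rkp <- list(list(c(1, 2), c(3, 4)), list(c(9, 8)))
  tr <- list(c(1, 9), 9)
  expect_equal(top_k_recall(rkp, tr, K = 2), 75)
  expect_error(top_k_recall(list(), list(), K = 1),
               class = "retentime_metric_error")
})

test_that("recall is non-decreasing in K on a fixed ranking set", {
  set.seed(70)
  rk <- lapply(1:50, function(i) sample(20))
  truth <- sample(20, 50, replace = TRUE)
  recalls <- vapply(1:20, function(k) top_k_recall(rk, truth, k), 1)
  expect_true(all(diff(recalls) >= 0))
  expect_equal(recalls[20], 100)
})

test_that("uniform random rankings score near the binomial chance level", {
  set.seed(71)
  n <- 1e4
  rk <- lapply(seq_len(n), function(i) sample(100))
  truth <- sample(100, n, replace = TRUE)
  r <- top_k_recall(rk, truth, K = 5)
  p0 <- 5 / 100
  se <- 100 * sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(r - 100 * p0), 3 * se)
})

test_that("auprc matches hand-computed step integrals", {
  # perfect separation
  perfect <- auprc_multilabel(matrix(c(0.9, 0.8, 0.2, 0.1), 4, 1),
                              matrix(c(1, 1, 0, 0), 4, 1))
  expect_equal(perfect$mean, 100)
  # constant scores collapse to a single threshold: AP = prevalence
  const <- auprc_multilabel(matrix(0.5, 10, 1),
                            matrix(c(rep(1, 3), rep(0, 7)), 10, 1))
  expect_equal(const$mean, 30)
  # 6-point list, scores desc: truths 1,0,1,1,0,0
  # thresholds give (R, P): (1/3, 1) (1/3, 1/2) (2/3, 2/3) (1, 3/4) (1, 3/5) (1, 1/2)
  # AP = 1/3 * 1 + 0 + 1/3 * 2/3 + 1/3 * 3/4 + 0 + 0 = 0.80555...
  hand <- 1 / 3 + (1 / 3) * (2 / 3) + (1 / 3) * (3 / 4)
  got <- auprc_multilabel(matrix(c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4), 6, 1),
                          matrix(c(1, 0, 1, 1, 0, 0), 6, 1))
  expect_equal(got$mean, 100 * hand)
  # labels without positives are skipped with a warning
  expect_warning(
    both <- auprc_multilabel(matrix(runif(12), 6, 2),
                             cbind(c(1, 0, 1, 1, 0, 0), 0)),
    "skipped")
  expect_true(is.na(both$per_label[2]))
})

test_that("the extrapolation sweep reports model and persistence MAE per horizon", {
  m <- tiny_cont_model(L = 1, d = 8, nh = 2, v = 1, seed = 72)
  m$train_length <- 64
  data <- generate_biosignal(biosignal_gen_config(n_series = 1, length = 96,
                                                  n_channels = 1, periods = 16,
                                                  seed = 72))
  sw <- run_extrapolation_sweep(m, data, lookup = 32, horizons = 16L)
  expect_equal(nrow(sw), 1L)
  expect_named(sw, c("horizon", "mae_model", "mae_persistence", "extrapolation",
                     "n_windows"))
  expect_false(sw$extrapolation)                    # 32 + 16 <= 64
  sw2 <- run_extrapolation_sweep(m, data, lookup = 32, horizons = c(16L, 64L))
  expect_true(sw2$extrapolation[2])                 # 32 + 64 > 64
  expect_true(all(is.finite(sw2$mae_persistence)))
})
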