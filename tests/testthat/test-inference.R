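test_that("streaming consumption reproduces the parallel forward pass exactly", {
  m <- tiny_cont_model(L = 2, d = 16, nh = 2, v = 3, seed = 50)
  set.seed(50)
  x <- matrix(rnorm(40 * 3), 40, 3)
  fw <- retentime:::model_forward(m, x)
  emb <- retentime:::embed_fwd(x, m$config, m$params)
  st <- model_stream_init(m)
  for (i in seq_len(nrow(emb$X))) {
    stp <- retentime:::model_stream_step(m, st, emb$X[i, ], emb$times[i],
                                         emb$times[i])
    st <- stp$state
    expect_lt(max(abs(stp$pred - fw$predictions[i, ])), 1e-10)
  }
  md <- tiny_disc_model(L = 2, d = 16, nh = 2, vocab = 8, seed = 51)
  ev <- random_events(15, 8, seed = 51)
  fwd <- retentime:::model_forward(md, ev)
  embd <- retentime:::embed_fwd(ev, md$config, md$params)
  enc <- retentime:::stream_consume(md, embd$X, embd$times)
  expect_lt(max(abs(enc$last$pred -
                      fwd$predictions[nrow(fwd$predictions), ])), 1e-10)
})

test_that("trajectory rollout handles the empty horizon and is deterministic", {
  m <- tiny_cont_model(L = 1, d = 8, nh = 2, v = 2, seed = 52)
  set.seed(52)
  x <- matrix(rnorm(32 * 2), 32, 2)
  empty <- forecast_trajectory(m, x, 0)
  expect_equal(nrow(empty$predictions), 0L)
  f1 <- forecast_trajectory(m, x, 12)
  f2 <- forecast_trajectory(m, x, 12)
  expect_identical(f1$predictions, f2$predictions)
  expect_equal(dim(f1$predictions), c(12L, 2L))
  expect_equal(f1$query_times, 32 + 1:12)
  expect_error(forecast_trajectory(m, x[0, , drop = FALSE], 4),
               class = "retentime_input_error")
})

test_that("a trained model extrapolates a noiseless sinusoid better than persistence", {
  data <- generate_biosignal(biosignal_gen_config(n_series = 6, length = 512,
                                                  n_channels = 1, periods = 64,
                                                  amplitudes = 1, noise_sd = 0,
                                                  phase_jitter = 1, seed = 53))
  m <- tiny_cont_model(L = 2, d = 32, nh = 4, v = 1, seed = 53)
  res <- pretrain_next_token(m, data,
                             train_config(epochs_pretrain = 40, batch_size = 4,
                                          learning_rate = 3e-3, seed = 53))
  test <- generate_biosignal(biosignal_gen_config(n_series = 1, length = 512,
                                                  n_channels = 1, periods = 64,
                                                  amplitudes = 1, noise_sd = 0,
                                                  phase_jitter = 1,
                                                  seed = 54))$series[[1]]
  prompt <- test[1:256, , drop = FALSE]
  target <- test[257:512, , drop = FALSE]
  fc <- forecast_trajectory(res$model, prompt, 256)
  expect_lt(mae(fc$predictions, target),
            mae(persistence_forecast(prompt, 256), target))
})

test_that("time-specific at the next grid point equals trajectory step one", {
  md <- tiny_disc_model(L = 2, d = 16, nh = 2, vocab = 8, seed = 55)
  ev <- event_sequence("p", as.numeric(1:12), sample(8, 12, replace = TRUE))
  tr <- forecast_trajectory(md, ev, horizon = 1, step = 1)
  ts <- forecast_time_specific(md, ev, 13)
  expect_lt(max(abs(tr$probabilities[1, ] - ts$probabilities[1, ])), 1e-6)
})

test_that("zero-gap queries preserve the state and ordering is enforced", {
  md <- tiny_disc_model(L = 1, d = 8, nh = 2, vocab = 5, seed = 56)
  ev <- random_events(10, 5, seed = 56)
  t_n <- ev$times[10]
  out <- forecast_time_specific(md, ev, c(t_n, t_n + 2))
  expect_equal(dim(out$probabilities), c(2L, 5L))
  expect_error(forecast_time_specific(md, ev, t_n - 1),
               class = "retentime_ordering_error")
})

test_that("rankings are permutations and probabilities are distributions", {
  md <- tiny_disc_model(L = 1, d = 8, nh = 2, vocab = 6, seed = 57)
  ev <- random_events(8, 6, seed = 57)
  out <- forecast_time_specific(md, ev, ev$times[8] + c(1, 5, 9))
  for (i in 1:3) {
    expect_setequal(out$rankings[[i]], 1:6)
    expect_equal(sum(out$probabilities[i, ]), 1)
    expect_true(all(out$probabilities[i, ] >= 0))
  }
})

test_that("growing gaps move the queried logits monotonically toward the forgetting limit", {
  md <- build_model(model_config(L = 1, d_model = 16, n_heads = 2,
                                 mode = "discrete", vocab_size = 8,
                                 use_temporal_conv = FALSE, seed = 58))
  ev <- random_events(12, 8, seed = 58)
  t_n <- ev$times[12]
  gaps <- c(1, 5, 20, 80, 320, 2000)
  # mechanism level: the queried state differs from the last-event-only state
  # K_N^T V_N by gamma^dt times the accumulated history, so the gap shrinks
  # monotonically and vanishes in the limit
  set.seed(58)
  dh <- 4
  st <- retention_state(dh)
  for (i in 1:10) {
    st <- retention_recurrent_step(rnorm(dh), rnorm(dh), rnorm(dh), st,
                                   dt = 1, gamma = 0.95)$state
  }
  q <- rnorm(dh); kN <- rnorm(dh); vN <- rnorm(dh)
  lim <- as.numeric(q %*% outer(kN, vN))
  dist <- vapply(gaps, function(g) {
    o <- retention_recurrent_step(q, kN, vN, st, dt = g, gamma = 0.95)$o
    sqrt(sum((o - lim)^2))
  }, 1)
  expect_true(all(diff(dist) < 0))
  expect_lt(dist[length(dist)], 1e-10)
  # model level: distances shrink overall and history is fully forgotten in
  # the limit (normalization layers make per-step monotonicity inexact)
  solo <- event_sequence("s", t_n, ev$codes[12])
  full <- forecast_time_specific(md, ev, t_n + gaps)$probabilities
  alone <- forecast_time_specific(md, solo, t_n + gaps)$probabilities
  mdist <- sqrt(rowSums((full - alone)^2))
  expect_lt(mdist[length(gaps)], 0.01 * max(mdist))
  expect_lt(max(abs(forecast_time_specific(md, ev, t_n + 1e7)$probabilities -
                      forecast_time_specific(md, solo, t_n + 1e7)$probabilities)),
            1e-8)
})

test_that("streaming state size is invariant to prompt length (O(1) queries)", {
  md <- tiny_disc_model(L = 2, d = 16, nh = 2, vocab = 8, seed = 59)
  sizes <- timings <- numeric(2)
  lens <- c(100, 1000)
  for (j in 1:2) {
    ev <- random_events(lens[j], 8, seed = 60 + j)
    pend <- retentime:::discrete_encode_pending(md, ev)
    sizes[j] <- stream_state_size(pend$state)
    timings[j] <- system.time(
      retentime:::discrete_query(md, pend, ev$times[lens[j]] + 1)
    )["elapsed"]
  }
  expect_equal(sizes[1], sizes[2])
  cat(sprintf("\n    single time-specific query: %.4fs (prompt 100) vs %.4fs (prompt 1000)\n",
              timings[1], timings[2]))
})

test_that("embedding export is deterministic with documented shape", {
  m <- tiny_cont_model(L = 1, d = 8, nh = 2, v = 1, seed = 61)
  set.seed(61)
  xs <- lapply(1:3, function(i) matrix(rnorm(24), 24, 1))
  xs[[3]] <- xs[[1]]
  emb <- export_embeddings(m, xs)
  expect_equal(dim(emb), c(3L, 8L))
  expect_equal(emb[1, ], emb[3, ])                  # identical inputs
  path <- tempfile(fileext = ".tsv")
  export_embeddings(m, xs, path)
  expect_true(file.exists(path))
  expect_equal(dim(as.matrix(utils::read.delim(path, header = FALSE))), c(3L, 8L))
})

test_that("embeddings of distinct-period classes are linearly separable after pre-training", {
  data <- lapply(1:24, function(i) {
    p <- c(24, 40)[(i %% 2) + 1]
    generate_biosignal(biosignal_gen_config(n_series = 1, length = 128,
                                            n_channels = 1, periods = p,
                                            amplitudes = 1, noise_sd = 0.1,
                                            phase_jitter = 1,
                                            seed = 700 + i))$series[[1]]
  })
  y <- rep(c(2, 1), 12)
  m <- tiny_cont_model(L = 2, d = 16, nh = 2, v = 1, seed = 62)
  res <- pretrain_next_token(m, data[1:12],
                             train_config(epochs_pretrain = 15, batch_size = 4,
                                          learning_rate = 3e-3, seed = 62))
  emb <- export_embeddings(res$model, data)
  train_idx <- 1:12; test_idx <- 13:24
  # nearest-centroid rule: a linear classifier fit on the training half
  cen1 <- colMeans(emb[train_idx[y[train_idx] == 1], ])
  cen2 <- colMeans(emb[train_idx[y[train_idx] == 2], ])
  pred <- apply(emb[test_idx, ], 1, function(e)
    which.min(c(sum((e - cen1)^2), sum((e - cen2)^2))))
  expect_gt(mean(pred == y[test_idx]), 0.9)
})
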