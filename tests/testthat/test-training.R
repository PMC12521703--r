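make_sine_data <- function(n = 4, len = 64, seed = 30) {
  generate_biosignal(biosignal_gen_config(n_series = n, length = len,
                                          n_channels = 1, periods = 16,
                                          amplitudes = 1, noise_sd = 0,
                                          phase_jitter = 1, seed = seed))
}

test_that("zero learning rate leaves the model and loss untouched", {
  m <- tiny_cont_model(L = 1, d = 8, nh = 2, v = 1, seed = 31)
  data <- make_sine_data()
  cfg <- train_config(epochs_pretrain = 3, batch_size = 2, learning_rate = 0,
                      seed = 1)
  res <- pretrain_next_token(m, data, cfg)
  expect_identical(res$model$params, m$params)
  expect_equal(res$loss_history, rep(res$loss_history[1], 3))
})

test_that("pre-training is deterministic and reduces the loss", {
  m <- tiny_cont_model(L = 2, d = 16, nh = 2, v = 1, seed = 32)
  data <- make_sine_data()
  cfg <- train_config(epochs_pretrain = 8, batch_size = 2, learning_rate = 3e-3,
                      seed = 2)
  r1 <- pretrain_next_token(m, data, cfg)
  r2 <- pretrain_next_token(m, data, cfg)
  expect_identical(r1$loss_history, r2$loss_history)
  expect_identical(r1$model$params, r2$model$params)
  expect_lt(r1$loss_history[8], r1$loss_history[1])
})

test_that("a 2-layer model fits noiseless sinusoids well below its initial loss", {
  m <- tiny_cont_model(L = 2, d = 16, nh = 2, v = 1, seed = 33)
  data <- make_sine_data(n = 4, len = 128)
  cfg <- train_config(epochs_pretrain = 50, batch_size = 2, learning_rate = 3e-3,
                      seed = 3)
  res <- pretrain_next_token(m, data, cfg)
  expect_lt(utils::tail(res$loss_history, 1), 0.1 * res$loss_history[1])
})

test_that("discrete pre-training reduces cross-entropy deterministically", {
  m <- tiny_disc_model(L = 1, d = 16, nh = 2, vocab = 6, seed = 34)
  seqs <- generate_event_sequences(event_gen_config(n_patients = 6,
                                                    vocab_size = 6,
                                                    mean_events = 15,
                                                    trend_codes = 1L,
                                                    seed = 9))
  cfg <- train_config(epochs_pretrain = 6, batch_size = 2, learning_rate = 3e-3,
                      loss = "cross_entropy", seed = 4)
  res <- pretrain_next_token(m, seqs, cfg)
  expect_lt(utils::tail(res$loss_history, 1), res$loss_history[1])
  expect_identical(pretrain_next_token(m, seqs, cfg)$loss_history,
                   res$loss_history)
})

test_that("gradients reach every parameter group in both modes and all heads", {
  mc <- tiny_cont_model(L = 1, d = 8, nh = 2, v = 1, seed = 35,
                        gated_output = TRUE)
  set.seed(5)
  expect_true(all(gradient_coverage(mc, matrix(rnorm(16), 16, 1))))
  md <- tiny_disc_model(L = 1, d = 8, nh = 2, vocab = 5, seed = 36)
  expect_true(all(gradient_coverage(md, random_events(8, 5))))
  mcls <- build_model(model_config(L = 1, d_model = 8, n_heads = 2,
                                   mode = "continuous", n_channels = 1,
                                   head = "classification", n_classes = 2,
                                   tc_kernel = 3, seed = 37))
  expect_true(all(gradient_coverage(mcls, list(x = matrix(rnorm(16), 16, 1), y = 1L),
                                    task = "classification")))
})

test_that("fine-tuning validates the head/task pairing and label range", {
  m <- tiny_cont_model(seed = 38)           # forecast head
  cfg <- train_config(task = "classification", seed = 1)
  expect_error(finetune(m, list(list(x = matrix(0, 8, 2), y = 1L)), cfg),
               class = "retentime_config_error")
  mc <- build_model(model_config(L = 1, d_model = 8, n_heads = 2,
                                 mode = "continuous", n_channels = 1,
                                 head = "classification", n_classes = 2,
                                 tc_kernel = 3, seed = 39))
  expect_error(finetune(mc, list(list(x = matrix(0, 8, 1), y = 5L)), cfg),
               class = "retentime_config_error")
})

test_that("a frozen control (zero learning rate) keeps metrics constant", {
  mc <- build_model(model_config(L = 1, d_model = 8, n_heads = 2,
                                 mode = "continuous", n_channels = 1,
                                 head = "classification", n_classes = 2,
                                 tc_kernel = 3, seed = 40))
  set.seed(6)
  labeled <- lapply(1:4, function(i)
    list(x = matrix(rnorm(16), 16, 1), y = (i %% 2L) + 1L))
  cfg <- train_config(epochs_finetune = 3, batch_size = 2, learning_rate = 0,
                      task = "classification", seed = 2)
  res <- finetune(mc, labeled, cfg)
  expect_equal(res$metric_history, rep(res$metric_history[1], 3))
  expect_identical(res$model$params, mc$params)
})

test_that("fine-tuning separates threshold-trend labels on held-out data", {
  tr <- run_pretrain_transfer_study(seeds = 1L, epochs_pretrain = 10L,
                                    epochs_finetune = 5L, n_labeled = 20L)
  expect_gt(tr$acc_pretrained[1], 0.9)
})

test_that("pre-training improves downstream accuracy versus scratch at equal budget", {
  tr <- run_pretrain_transfer_study(seeds = 1:5, epochs_pretrain = 20L,
                                    epochs_finetune = 5L, n_labeled = 8L,
                                    noise_sd = 0.2, class_by = "period")
  expect_gt(mean(tr$acc_pretrained), mean(tr$acc_scratch))
})

test_that("the scaling sweep returns a complete, finite grid", {
  sw <- run_scaling_sweep(d_models = 16L, n_series_grid = c(2L, 4L),
                          epochs = 3L, seed = 1L)
  expect_equal(nrow(sw), 2L)
  expect_true(all(is.finite(sw$val_loss)))
})
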