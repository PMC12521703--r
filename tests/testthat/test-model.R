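test_that("parameter count formula matches the built model across configurations", {
  configs <- list(
    model_config(L = 2, d_model = 16, n_heads = 2, mode = "continuous", n_channels = 3),
    model_config(L = 1, d_model = 8, n_heads = 2, mode = "continuous", n_channels = 1,
                 use_subsampling = FALSE, gated_output = TRUE),
    model_config(L = 2, d_model = 16, n_heads = 4, mode = "discrete", vocab_size = 9,
                 tc_configuration = "PW+DW+PW"),
    model_config(L = 1, d_model = 8, n_heads = 2, mode = "discrete", vocab_size = 5,
                 use_rope = FALSE, use_decay = FALSE, max_positions = 64,
                 use_temporal_conv = FALSE),
    model_config(L = 1, d_model = 8, n_heads = 2, mode = "continuous", n_channels = 2,
                 head = "classification", n_classes = 3, use_ffn = FALSE)
  )
  for (cfg in configs) {
    m <- build_model(cfg)
    expect_equal(retentime:::param_reduce(length, m$params), param_count(cfg))
  }
  expect_error(model_config(L = 1, d_model = 9, n_heads = 2, mode = "continuous",
                            n_channels = 1),
               class = "retentime_config_error")
  expect_error(model_config(L = 1, d_model = 8, n_heads = 2, mode = "continuous",
                            n_channels = 1, use_decay = TRUE, use_rope = FALSE),
               class = "retentime_config_error")
})

test_that("embedding adds [SOS] and maps repeated codes identically", {
  m <- tiny_disc_model()
  ev <- random_events(9, 8, seed = 5)
  ev$codes[4] <- ev$codes[2]
  e <- embed_input(ev, m$config, m$params)
  expect_equal(dim(e$X), c(10L, 16L))
  expect_equal(e$X[3, ], e$X[5, ])                 # same code, same row
  expect_equal(e$token_times, c(ev$times[1] - 1, ev$times))
  expect_true(all(diff(e$token_times) > 0))
})

test_that("a 4000-step continuous input embeds to 1001 tokens including [SOS]", {
  m <- tiny_cont_model(L = 1, d = 8, nh = 2, v = 1, seed = 2)
  x <- matrix(sin(seq_len(4000) / 10), 4000, 1)
  e <- embed_input(x, m$config, m$params)
  expect_equal(nrow(e$X), 1001L)
})

test_that("mode and input kind must match", {
  m <- tiny_cont_model()
  expect_error(forward(m, random_events(5, 8)), class = "retentime_config_error")
  md <- tiny_disc_model()
  expect_error(forward(md, matrix(0, 10, 2)), class = "retentime_config_error")
  bad <- random_events(5, 8)
  bad$codes[2] <- 99L
  expect_error(forward(md, bad), class = "retentime_config_error")
})

test_that("decoder layer preserves shape and causality for every toggle set", {
  d <- 16
  set.seed(6)
  X <- matrix(rnorm(24 * d), 24, d)
  variants <- list(
    model_config(L = 1, d_model = d, n_heads = 2, mode = "continuous",
                 n_channels = 1, tc_kernel = 5),
    model_config(L = 1, d_model = d, n_heads = 2, mode = "continuous",
                 n_channels = 1, use_temporal_conv = FALSE),
    model_config(L = 1, d_model = d, n_heads = 2, mode = "continuous",
                 n_channels = 1, use_decay = FALSE, tc_kernel = 5),
    model_config(L = 1, d_model = d, n_heads = 2, mode = "continuous",
                 n_channels = 1, use_rope = FALSE, use_decay = FALSE,
                 tc_kernel = 5, tc_norm = "none")
  )
  for (cfg in variants) {
    lw <- build_model(cfg)$params$layers[[1]]
    y <- decoder_layer(X, lw, cfg)
    expect_equal(dim(y), dim(X))
    X2 <- X; X2[17:24, ] <- 3
    y2 <- decoder_layer(X2, lw, cfg)
    expect_equal(y2[1:16, ], y[1:16, ], tolerance = 1e-12)
  }
})

test_that("forward produces finite outputs of the documented shapes", {
  m <- tiny_cont_model(L = 1, d = 8, nh = 2, v = 2, seed = 3)
  x <- matrix(rnorm(32 * 2), 32, 2)
  fw <- forward(m, x)
  expect_equal(dim(fw$representations), c(9L, 8L))  # 8 tokens + SOS
  expect_equal(dim(fw$predictions), c(9L, 4 * 2))   # next 4 raw steps x V
  expect_true(all(is.finite(fw$predictions)))
  mc <- build_model(model_config(L = 1, d_model = 8, n_heads = 2,
                                 mode = "continuous", n_channels = 2,
                                 head = "classification", n_classes = 3,
                                 tc_kernel = 5, seed = 4))
  expect_length(forward(mc, x)$predictions, 3)
  mr <- build_model(model_config(L = 1, d_model = 8, n_heads = 2,
                                 mode = "continuous", n_channels = 2,
                                 head = "regression", tc_kernel = 5, seed = 4))
  expect_length(forward(mr, x)$predictions, 1)
})

test_that("full-model forward agrees across retention forms with shared weights", {
  m <- tiny_disc_model(L = 2, d = 16, nh = 2, vocab = 8, seed = 9)
  ev <- random_events(40, 8, seed = 6)
  outs <- lapply(c("parallel", "recurrent", "chunkwise"), function(f)
    retentime:::model_forward(m, ev, form = f)$predictions)
  expect_lt(rel_err(outs[[1]], outs[[2]]), 1e-10)
  expect_lt(rel_err(outs[[1]], outs[[3]]), 1e-10)
})

test_that("the sequence model is order-sensitive, unlike a bag-of-codes pooling", {
  m <- build_model(model_config(L = 1, d_model = 16, n_heads = 2,
                                mode = "discrete", vocab_size = 8,
                                head = "classification", n_classes = 2,
                                tc_kernel = 5, seed = 10))
  ev <- random_events(12, 8, seed = 8)
  rev_ev <- event_sequence("p1", ev$times, rev(ev$codes))
  logits_fwd <- forward(m, ev)$predictions
  logits_rev <- forward(m, rev_ev)$predictions
  expect_false(isTRUE(all.equal(logits_fwd, logits_rev)))
  # a bag-of-codes readout (mean codebook row through the same head) is
  # permutation-invariant by construction
  bag <- function(e) colMeans(m$params$codebook[e$codes, , drop = FALSE]) %*%
    m$params$head$W
  expect_equal(bag(ev), bag(rev_ev))
})

test_that("every ablation variant of the toggle grid trains without code changes", {
  grids <- list(c(TRUE, TRUE, TRUE, TRUE), c(FALSE, TRUE, TRUE, TRUE),
                c(TRUE, FALSE, TRUE, TRUE), c(TRUE, TRUE, FALSE, TRUE),
                c(TRUE, TRUE, FALSE, FALSE))
  set.seed(20)
  x <- matrix(rnorm(32), 32, 1)
  for (g in grids) {
    cfg <- model_config(L = 1, d_model = 8, n_heads = 2, mode = "continuous",
                        n_channels = 1, use_subsampling = g[1],
                        use_temporal_conv = g[2], use_decay = g[3],
                        use_rope = g[4], tc_kernel = 3, max_positions = 64,
                        seed = 5)
    res <- pretrain_next_token(build_model(cfg), list(x),
                               train_config(epochs_pretrain = 2, batch_size = 1,
                                            learning_rate = 1e-3, seed = 1))
    expect_true(all(is.finite(res$loss_history)))
  }
})

test_that("checkpoints round-trip bit-exactly", {
  m <- tiny_cont_model(seed = 21)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m$params, m2$params)
  expect_identical(m$buffers, m2$buffers)
  expect_identical(unclass(m$config), unclass(m2$config))
  x <- matrix(rnorm(20), 20, 2)
  expect_identical(forward(m, x)$predictions, forward(m2, x)$predictions)
})

test_that("analytic gradients match finite differences through the full stack", {
  cfg <- model_config(L = 1, d_model = 8, n_heads = 2, mode = "continuous",
                      n_channels = 2, tc_kernel = 3, gated_output = TRUE,
                      seed = 7)
  m <- build_model(cfg)
  set.seed(1)
  x <- matrix(rnorm(16 * 2), 16, 2)
  g <- retentime:::pretrain_seq_grads(m, x)
  eps <- 1e-6
  probe <- list(list("layers", 1L, "ret", "W_Q"), list("tok", "W1"),
                list("layers", 1L, "tc", "dw", "W"), list("head", "W"),
                list("sos"))
  get_leaf <- function(tree, pa) Reduce(`[[`, pa, tree)
  set_leaf <- function(tree, pa, i, val) {
    expr <- "tree"
    for (p in pa) expr <- sprintf("%s[[%s]]", expr,
                                  if (is.character(p)) shQuote(p) else p)
    eval(parse(text = sprintf("%s[i] <- val", expr)))
    tree
  }
  for (pa in probe) {
    leaf <- get_leaf(m$params, pa)
    i <- max(1L, length(leaf) %/% 2L)
    m2 <- m
    m2$params <- set_leaf(m2$params, pa, i, leaf[i] + eps)
    lp <- retentime:::pretrain_seq_grads(m2, x)$loss
    m2$params <- set_leaf(m2$params, pa, i, leaf[i] - eps)
    lm <- retentime:::pretrain_seq_grads(m2, x)$loss
    num <- (lp - lm) / (2 * eps)
    ana <- get_leaf(g$grads, pa)[i]
    expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-5)
  }
})
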