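test_that("single-token retention reduces to the rank-one product", {
  set.seed(1)
  d <- 8
  X <- matrix(rnorm(d), 1, d)
  w <- tiny_weights(d)
  ang <- rotation_angles(d)
  out <- retention_parallel(X, w, ang, 0.9)
  q <- apply_rotation(X %*% w$W_Q, 0, ang)
  k <- apply_rotation(X %*% w$W_K, 0, ang)
  v <- X %*% w$W_V
  expect_equal(out, as.numeric(q %*% t(k)) * v)
})

test_that("parallel retention matches the brute-force masked-decay sum", {
  set.seed(7)
  n <- 7; d <- 8; nh <- 2; dh <- d / nh
  X <- matrix(rnorm(n * d), n, d)
  w <- tiny_weights(d)
  ang <- rotation_angles(dh)
  g <- head_decay_rates(nh)
  ts <- cumsum(runif(n, 0.2, 2))
  out <- retention_parallel(X, w, ang, g, ts)
  Q <- X %*% w$W_Q; K <- X %*% w$W_K; V <- X %*% w$W_V
  for (h in 1:nh) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    qh <- apply_rotation(Q[, cols, drop = FALSE], ts, ang)
    kh <- apply_rotation(K[, cols, drop = FALSE], ts, ang)
    ref <- oracle_retention_head(qh, kh, V[, cols, drop = FALSE], g$gamma[h], ts)
    expect_lt(rel_err(out[, cols], ref), 1e-10)
  }
})

test_that("retention output is causal: later inputs never affect earlier rows", {
  set.seed(8)
  n <- 12; d <- 8
  X <- matrix(rnorm(n * d), n, d)
  w <- tiny_weights(d)
  ang <- rotation_angles(4)
  g <- head_decay_rates(2)
  base <- retention_parallel(X, w, ang, g, normalize = TRUE)
  for (cut in c(4, 9)) {
    X2 <- X
    X2[(cut + 1):n, ] <- rnorm((n - cut) * d) * 3
    pert <- retention_parallel(X2, w, ang, g, normalize = TRUE)
    expect_equal(pert[1:cut, ], base[1:cut, ])
  }
})

test_that("recurrent step implements the decayed state update", {
  set.seed(2)
  dh <- 4
  q1 <- rnorm(dh); k1 <- rnorm(dh); v1 <- rnorm(dh)
  st <- retention_state(dh)
  s1 <- retention_recurrent_step(q1, k1, v1, st, dt = 1, gamma = 0.9)
  expect_equal(s1$state$S, outer(k1, v1))          # S_1 = K_1^T V_1
  expect_equal(s1$o, as.numeric(q1 %*% outer(k1, v1)))
  # huge gap forgets all history
  k2 <- rnorm(dh); v2 <- rnorm(dh)
  s2 <- retention_recurrent_step(q1, k2, v2, s1$state, dt = 1e6, gamma = 0.9)
  fresh <- retention_recurrent_step(q1, k2, v2, retention_state(dh), dt = 0,
                                    gamma = 0.9)
  expect_equal(s2$state$S, fresh$state$S)
  expect_equal(s2$o, fresh$o)
  expect_error(retention_recurrent_step(q1, k1, v1, st, dt = -1, gamma = 0.9),
               class = "retentime_ordering_error")
})

test_that("parallel, recurrent and chunk-wise forms agree across sizes and chunkings", {
  set.seed(21)
  ang <- rotation_angles(8)
  g <- head_decay_rates(4)
  for (n in c(16, 100)) {
    for (irregular in c(FALSE, TRUE)) {
      d <- 32
      X <- matrix(rnorm(n * d), n, d)
      w <- tiny_weights(d, seed = n)
      ts <- if (irregular) cumsum(runif(n, 0.1, 3)) else NULL
      for (norm in c(FALSE, TRUE)) {
        p <- retention_parallel(X, w, ang, g, ts, normalize = norm)
        r <- retentime:::retention_recurrent(X, w, ang, g, ts, normalize = norm)
        expect_lt(rel_err(p, r), 1e-10)
        for (cs in c(1, 7, n)) {
          ck <- retention_chunkwise(X, w, ang, g, ts, chunk_size = cs,
                                    normalize = norm)
          expect_lt(rel_err(p, ck), 1e-10)
        }
      }
    }
  }
})

test_that("a recurrent sweep with unit gaps reproduces integer-grid retention exactly", {
  set.seed(3)
  n <- 16; d <- 16
  X <- matrix(rnorm(n * d), n, d)
  w <- tiny_weights(d)
  ang <- rotation_angles(8)
  g <- head_decay_rates(2)
  grid <- retention_parallel(X, w, ang, g, NULL)
  unit <- retentime:::retention_recurrent(X, w, ang, g, as.numeric(0:(n - 1)))
  expect_lt(rel_err(grid, unit), 1e-10)
})

test_that("six recurrent steps agree with chunked evaluation at chunk size two", {
  set.seed(4)
  n <- 6; d <- 8
  X <- matrix(rnorm(n * d), n, d)
  w <- tiny_weights(d)
  ang <- rotation_angles(4)
  g <- head_decay_rates(2)
  r <- retentime:::retention_recurrent(X, w, ang, g, NULL)
  ck <- retention_chunkwise(X, w, ang, g, NULL, chunk_size = 2)
  expect_lt(rel_err(r, ck), 1e-10)
})

test_that("multi-head dispatch agrees across forms and degenerates to one head", {
  set.seed(9)
  n <- 20; d <- 16
  X <- matrix(rnorm(n * d), n, d)
  w <- projection_weights(d, seed = 2, gated = TRUE, out_proj = TRUE)
  outs <- lapply(c("parallel", "recurrent", "chunkwise"), function(f) {
    cfg <- retention_config(d, 2, chunk_size = 6, form = f, gated_output = TRUE)
    multi_head_retention(X, cfg, w)
  })
  expect_lt(rel_err(outs[[1]], outs[[2]]), 1e-10)
  expect_lt(rel_err(outs[[1]], outs[[3]]), 1e-10)
  one <- multi_head_retention(X, retention_config(d, 1), w)
  ang <- rotation_angles(d)
  ref <- retention_parallel(X, w, ang, head_decay_rates(1), normalize = TRUE)
  ref <- retentime:::group_norm_heads(ref, 1) %*% w$W_O
  expect_lt(rel_err(one, ref), 1e-10)
})

test_that("recurrent per-step cost does not grow with history length", {
  # the state carries a fixed number of values regardless of steps consumed
  set.seed(10)
  dh <- 8
  st <- retention_state(dh)
  sizes <- integer(0)
  for (i in 1:50) {
    st <- retention_recurrent_step(rnorm(dh), rnorm(dh), rnorm(dh), st,
                                   dt = 1, gamma = 0.95)$state
    sizes <- c(sizes, length(st$S) + length(st$r))
  }
  expect_equal(unique(sizes), dh * dh + 1L)
})

test_that("causal softmax attention matches its brute-force oracle", {
  set.seed(11)
  d <- 6
  X1 <- matrix(rnorm(d), 1, d)
  w <- tiny_weights(d)
  expect_equal(causal_softmax_attention(X1, w), X1 %*% w$W_V)  # softmax of one
  X <- matrix(rnorm(5 * d), 5, d)
  expect_lt(rel_err(causal_softmax_attention(X, w), oracle_softmax_attention(X, w)),
            1e-10)
  # attention rows are proper distributions
  Q <- X %*% w$W_Q; K <- X %*% w$W_K
  s <- (Q %*% t(K)) / sqrt(d)
  s[upper.tri(s)] <- -Inf
  P <- retentime:::softmax_rows(s)
  expect_equal(rowSums(P), rep(1, 5))
})
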