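# Shared fixtures and independent oracles for the suite.

tiny_weights <- function(d, seed = 3L, ...) projection_weights(d, seed = seed, ...)

random_events <- function(n, vocab, seed = 1L, rate = 0.5) {
  set.seed(seed)
  event_sequence("p1", cumsum(stats::rexp(n, rate) + 1e-3),
                 sample.int(vocab, n, replace = TRUE))
}

tiny_cont_model <- function(L = 2L, d = 16L, nh = 2L, v = 2L, seed = 11L, ...) {
  build_model(model_config(L = L, d_model = d, n_heads = nh,
                           mode = "continuous", n_channels = v,
                           tc_kernel = 5L, seed = seed, ...))
}

tiny_disc_model <- function(L = 2L, d = 16L, nh = 2L, vocab = 8L, seed = 12L, ...) {
  build_model(model_config(L = L, d_model = d, n_heads = nh, mode = "discrete",
                           vocab_size = vocab, tc_kernel = 5L, seed = seed, ...))
}

# Brute-force unnormalized retention (the literal masked-decay sum), one head.
oracle_retention_head <- function(qh, kh, vh, gamma, ts) {
  n <- nrow(qh)
  out <- matrix(0, n, ncol(vh))
  for (i in seq_len(n)) {
    for (m in seq_len(i)) {
      out[i, ] <- out[i, ] +
        gamma^(ts[i] - ts[m]) * sum(qh[i, ] * kh[m, ]) * vh[m, ]
    }
  }
  out
}

# Brute-force per-row causal softmax attention, single head.
oracle_softmax_attention <- function(X, w) {
  Q <- X %*% w$W_Q; K <- X %*% w$W_K; V <- X %*% w$W_V
  d <- ncol(X)
  out <- matrix(0, nrow(X), d)
  for (i in seq_len(nrow(X))) {
    s <- as.numeric(Q[i, ] %*% t(K[seq_len(i), , drop = FALSE])) / sqrt(d)
    p <- exp(s - max(s)); p <- p / sum(p)
    out[i, ] <- as.numeric(p %*% V[seq_len(i), , drop = FALSE])
  }
  out
}

rel_err <- function(a, b) max(abs(a - b)) / max(1e-12, max(abs(a)))
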