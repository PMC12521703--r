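# Differentiable building blocks (forward + hand-written backward) and the
# Adam optimizer. Parameters live in nested named lists; gradients mirror the
# structure exactly.

LN_EPS <- 1e-5
BN_EPS <- 1e-5

# ---- parameter-tree utilities ----------------------------------------------

# Apply f elementwise over two parameter trees with identical shape. Named
# lists are matched by name (order-independent); unnamed lists by position.
param_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    keys <- names(a) %||% seq_along(a)
    for (nm in keys) out[[nm]] <- param_map2(f, a[[nm]], b[[nm]])
    out
  } else {
    f(a, b)
  }
}

param_map <- function(f, a) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    keys <- names(a) %||% seq_along(a)
    for (nm in keys) out[[nm]] <- param_map(f, a[[nm]])
    out
  } else {
    f(a)
  }
}

zero_like <- function(a) param_map(function(x) x * 0, a)

add_trees <- function(a, b) param_map2(`+`, a, b)

# Sum of a function applied to every leaf (e.g. for global grad norm).
param_reduce <- function(f, a, acc = 0) {
  if (is.list(a)) {
    for (el in a) acc <- param_reduce(f, el, acc)
    acc
  } else {
    acc + f(a)
  }
}

n_leaves_values <- function(a) param_reduce(length, a)

# ---- dense / activation layers ---------------------------------------------

linear_fwd <- function(x, W, b = NULL) {
  y <- x %*% W
  if (!is.null(b)) y <- y + row_broadcast(b, nrow(y))
  y
}

linear_bwd <- function(dy, x, W, has_bias = TRUE) {
  list(dx = dy %*% t(W), dW = t(x) %*% dy,
       db = if (has_bias) colSums(dy) else NULL)
}

swish_fwd <- function(x) list(y = swish(x), x = x)
swish_bwd <- function(dy, cache) dy * swish_grad(cache$x)

# ---- layer norm -------------------------------------------------------------

layer_norm_fwd <- function(x, g, b, eps = LN_EPS) {
  mu <- rowMeans(x)
  v <- rowMeans(x^2) - mu^2
  inv <- 1 / sqrt(v + eps)
  xhat <- (x - mu) * inv
  y <- xhat * row_broadcast(g, nrow(x)) + row_broadcast(b, nrow(x))
  list(y = y, xhat = xhat, inv = inv)
}

layer_norm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  n <- nrow(dy)
  dxhat <- dy * row_broadcast(g, n)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

# Per-head group norm (no affine): normalize each head block per row.
group_norm_fwd <- function(x, n_heads, eps = 1e-6) {
  d <- ncol(x); dh <- d %/% n_heads
  y <- x
  caches <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- head_cols(h, dh)
    blk <- x[, cols, drop = FALSE]
    mu <- rowMeans(blk)
    v <- rowMeans(blk^2) - mu^2
    inv <- 1 / sqrt(v + eps)
    xhat <- (blk - mu) * inv
    y[, cols] <- xhat
    caches[[h]] <- list(xhat = xhat, inv = inv)
  }
  list(y = y, caches = caches, n_heads = n_heads)
}

group_norm_bwd <- function(dy, cache) {
  nh <- cache$n_heads
  d <- ncol(dy); dh <- d %/% nh
  dx <- dy
  for (h in seq_len(nh)) {
    cols <- head_cols(h, dh)
    ch <- cache$caches[[h]]
    dyh <- dy[, cols, drop = FALSE]
    m1 <- rowMeans(dyh)
    m2 <- rowMeans(dyh * ch$xhat)
    dx[, cols] <- ch$inv * (dyh - m1 - ch$xhat * m2)
  }
  dx
}

# ---- batch norm (per channel over positions) --------------------------------

batch_norm_fwd <- function(x, g, b, running, training, momentum = 0.1,
                           eps = BN_EPS) {
  n <- nrow(x)
  if (training && n > 1L) {
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
    v <- pmax(v, 0)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v * n / max(n - 1L, 1L)
  } else {
    mu <- running$mean
    v <- running$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (x - row_broadcast(mu, n)) * row_broadcast(inv, n)
  y <- xhat * row_broadcast(g, n) + row_broadcast(b, n)
  list(y = y, xhat = xhat, inv = inv, running = running,
       batch_stats = training && n > 1L)
}

batch_norm_bwd <- function(dy, cache, g) {
  n <- nrow(dy)
  dxhat <- dy * row_broadcast(g, n)
  dg <- colSums(dy * cache$xhat)
  db <- colSums(dy)
  if (cache$batch_stats) {
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * cache$xhat)
    dx <- row_broadcast(cache$inv, n) *
      (dxhat - row_broadcast(m1, n) - cache$xhat * row_broadcast(m2, n))
  } else {
    dx <- dxhat * row_broadcast(cache$inv, n)
  }
  list(dx = dx, dg = dg, db = db)
}

# ---- 1-D convolutions (causal left padding) ---------------------------------

# x: T x Cin; W: k x Cin x Cout; output length floor((T-1)/stride) + 1.
conv1d_fwd <- function(x, W, b, stride = 1L) {
  T_in <- nrow(x)
  k <- dim(W)[1]; cin <- dim(W)[2]; cout <- dim(W)[3]
  p <- k - 1L
  xp <- rbind(matrix(0, p, cin), x)
  nout <- (T_in - 1L) %/% stride + 1L
  y <- row_broadcast(b, nout)
  for (u in seq_len(k)) {
    rows <- stride * (seq_len(nout) - 1L) + u
    y <- y + xp[rows, , drop = FALSE] %*% matrix(W[u, , ], cin, cout)
  }
  list(y = y, xp = xp, T_in = T_in, stride = stride)
}

conv1d_bwd <- function(dy, cache, W) {
  k <- dim(W)[1]; cin <- dim(W)[2]; cout <- dim(W)[3]
  p <- k - 1L
  nout <- nrow(dy)
  stride <- cache$stride
  dxp <- matrix(0, nrow(cache$xp), cin)
  dW <- array(0, dim(W))
  for (u in seq_len(k)) {
    rows <- stride * (seq_len(nout) - 1L) + u
    Wu <- matrix(W[u, , ], cin, cout)
    dxp[rows, ] <- dxp[rows, , drop = FALSE] + dy %*% t(Wu)
    dW[u, , ] <- t(cache$xp[rows, , drop = FALSE]) %*% dy
  }
  list(dx = dxp[(p + 1L):(p + cache$T_in), , drop = FALSE], dW = dW,
       db = colSums(dy))
}

# Depth-wise conv: one kernel column per channel. W: k x d; stride 1.
dwconv_fwd <- function(x, W, b) {
  T_in <- nrow(x); d <- ncol(x)
  k <- nrow(W)
  p <- k - 1L
  xp <- rbind(matrix(0, p, d), x)
  y <- row_broadcast(b, T_in)
  for (u in seq_len(k)) {
    rows <- (seq_len(T_in) - 1L) + u
    y <- y + xp[rows, , drop = FALSE] * row_broadcast(W[u, ], T_in)
  }
  list(y = y, xp = xp, T_in = T_in)
}

dwconv_bwd <- function(dy, cache, W) {
  k <- nrow(W); d <- ncol(W)
  T_in <- cache$T_in
  p <- k - 1L
  dxp <- matrix(0, nrow(cache$xp), d)
  dW <- matrix(0, k, d)
  for (u in seq_len(k)) {
    rows <- (seq_len(T_in) - 1L) + u
    dxp[rows, ] <- dxp[rows, , drop = FALSE] + dy * row_broadcast(W[u, ], T_in)
    dW[u, ] <- colSums(cache$xp[rows, , drop = FALSE] * dy)
  }
  list(dx = dxp[(p + 1L):(p + T_in), , drop = FALSE], dW = dW, db = colSums(dy))
}

# ---- losses -----------------------------------------------------------------

mse_loss <- function(pred, target) {
  diff <- pred - target
  list(loss = mean(diff^2), dpred = 2 * diff / length(diff))
}

# logits: N x C; targets: integer vector in 1..C. Positions with NA target are
# masked out of the loss.
cross_entropy_loss <- function(logits, targets) {
  keep <- which(!is.na(targets))
  P <- softmax_rows(logits)
  n <- length(keep)
  idx <- cbind(keep, targets[keep])
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  dlogits <- matrix(0, nrow(logits), ncol(logits))
  dlogits[keep, ] <- P[keep, , drop = FALSE] / n
  dlogits[idx] <- dlogits[idx] - 1 / n
  list(loss = loss, dpred = dlogits)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

# Returns list(params, state). lr already schedule-adjusted by the caller.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- param_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- param_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                    state$m, state$v)
  params <- param_map2(`-`, params, upd)
  list(params = params, state = state)
}

# Linear warmup then cosine decay to 10% of peak.
lr_schedule <- function(step, total_steps, lr, warmup_frac = 0.1) {
  warm <- max(1, floor(total_steps * warmup_frac))
  if (step <= warm) return(lr * step / warm)
  prog <- (step - warm) / max(1, total_steps - warm)
  lr * (0.1 + 0.9 * 0.5 * (1 + cos(pi * min(prog, 1))))
}

# Global-norm gradient clipping.
clip_grads <- function(grads, max_norm = 1.0) {
  total <- sqrt(param_reduce(function(g) sum(g^2), grads))
  if (is.finite(total) && total > max_norm) {
    grads <- param_map(function(g) g * (max_norm / total), grads)
  }
  grads
}
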