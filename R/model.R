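# Decoder-only model assembly: input embedding (conv tokenizer for continuous
# signals, learnable codebook for discrete codes), L decoder layers
# (retention -> temporal convolution -> feed-forward, pre-norm residuals),
# and task heads. All ablation toggles are plain config switches.

#' Model configuration
#'
#' @param L Number of decoder layers.
#' @param d_model Model width (divisible by `n_heads`; head width even).
#' @param n_heads Retention heads.
#' @param mode `"continuous"` (biosignal matrices) or `"discrete"`
#'   (timestamped code sequences).
#' @param n_channels Input channels `V` (continuous mode).
#' @param vocab_size Code vocabulary size (discrete mode).
#' @param head Task head: `"forecast"`, `"classification"` or `"regression"`.
#' @param n_classes Class count for the classification head.
#' @param retention_form Computational form used at inference-time forward
#'   passes: `"parallel"`, `"recurrent"` or `"chunkwise"` (training always
#'   differentiates the parallel form; all forms agree numerically).
#' @param chunk_size Chunk length for the chunk-wise form (default 512).
#' @param use_subsampling Convolution-subsampling tokenizer on raw input
#'   (continuous mode; off embeds every raw timestep).
#' @param use_temporal_conv Temporal convolution sublayer in each decoder layer.
#' @param use_decay Exponential decay mask (requires `use_rope`); off sets all
#'   head decay rates to 1 (plain causal mask).
#' @param use_rope Rotary position embedding + retention; off falls back to
#'   causal softmax attention with sinusoidal absolute positions (the plain
#'   GPT-2 ablation).
#' @param normalize Retention stabilization (decay-mass row scaling + per-head
#'   group norm).
#' @param gated_output Swish output gate on head outputs (default off).
#' @param d_ff Feed-forward inner width (default `2 * d_model`).
#' @param use_ffn Include the position-wise feed-forward sublayer.
#' @param tc_kernel Depth-wise kernel width of the temporal convolution.
#' @param tc_configuration Temporal convolution layout (see
#'   [temporal_conv_config()]).
#' @param tc_norm `"batch"` or `"none"` inside the temporal convolution block.
#' @param max_positions Size of the learned absolute-position table used by
#'   the no-rotary ablation (positions past the training length remain at
#'   their random initialization).
#' @param rotation_base Rotary angle-schedule base.
#' @param rotate_by_time In discrete mode, rotate by real timestamps (TRUE,
#'   consistent with time-gap decay) or by ordinal index (FALSE).
#' @param seed Seed from which every weight initialization flows.
#' @return Object of class `model_config`.
#' @export
model_config <- function(L, d_model, n_heads,
                         mode = c("continuous", "discrete"),
                         n_channels = NULL, vocab_size = NULL,
                         head = c("forecast", "classification", "regression"),
                         n_classes = NULL,
                         retention_form = c("parallel", "recurrent", "chunkwise"),
                         chunk_size = 512L,
                         use_subsampling = TRUE, use_temporal_conv = TRUE,
                         use_decay = TRUE, use_rope = TRUE,
                         normalize = TRUE, gated_output = FALSE,
                         d_ff = NULL, use_ffn = TRUE,
                         tc_kernel = 15L,
                         tc_configuration = "DW+PW", tc_norm = "batch",
                         max_positions = 1024L,
                         rotation_base = 10000, rotate_by_time = TRUE,
                         seed = 1L) {
  mode <- match.arg(mode)
  head <- match.arg(head)
  retention_form <- match.arg(retention_form)
  rt_check(is_count(L, 1L), "`L` must be >= 1", "config_error")
  rt_check(is_count(d_model) && is_count(n_heads) && d_model %% n_heads == 0L,
           "`d_model` must be a positive multiple of `n_heads`", "config_error")
  rt_check((d_model %/% n_heads) %% 2L == 0L, "head width must be even",
           "config_error")
  rt_check(!(use_decay && !use_rope),
           "`use_decay` requires `use_rope` (decay is part of the rotary-decay embedding)",
           "config_error")
  if (mode == "continuous") {
    rt_check(is_count(n_channels, 1L), "continuous mode requires `n_channels`",
             "config_error")
  } else {
    rt_check(is_count(vocab_size, 2L), "discrete mode requires `vocab_size` >= 2",
             "config_error")
    use_subsampling <- FALSE
  }
  if (head == "classification") {
    rt_check(is_count(n_classes, 2L), "classification head requires `n_classes` >= 2",
             "config_error")
  }
  d_ff <- as.integer(d_ff %||% (2L * d_model))
  patch <- if (mode == "continuous" && use_subsampling) 4L else 1L
  structure(list(
    L = as.integer(L), d_model = as.integer(d_model), n_heads = as.integer(n_heads),
    d_head = as.integer(d_model %/% n_heads), mode = mode,
    n_channels = if (is.null(n_channels)) NULL else as.integer(n_channels),
    vocab_size = if (is.null(vocab_size)) NULL else as.integer(vocab_size),
    head = head, n_classes = if (is.null(n_classes)) NULL else as.integer(n_classes),
    retention_form = retention_form, chunk_size = as.integer(chunk_size),
    use_subsampling = isTRUE(use_subsampling),
    use_temporal_conv = isTRUE(use_temporal_conv),
    use_decay = isTRUE(use_decay), use_rope = isTRUE(use_rope),
    normalize = isTRUE(normalize), gated_output = isTRUE(gated_output),
    d_ff = d_ff, use_ffn = isTRUE(use_ffn),
    tc_kernel = as.integer(tc_kernel), tc_configuration = tc_configuration,
    tc_norm = tc_norm, max_positions = as.integer(max_positions),
    rotation_base = rotation_base,
    rotate_by_time = isTRUE(rotate_by_time), patch = patch,
    seed = as.integer(seed)
  ), class = "model_config")
}

model_gammas <- function(config) {
  if (config$use_decay) head_decay_rates(config$n_heads)$gamma
  else rep(1, config$n_heads)
}

model_tok_config <- function(config) tokenizer_config()

model_tc_config <- function(config) {
  temporal_conv_config(kernel_size = config$tc_kernel,
                       configuration = config$tc_configuration,
                       norm = config$tc_norm)
}

head_out_dim <- function(config) {
  switch(config$head,
    forecast = if (config$mode == "continuous") config$patch * config$n_channels
               else config$vocab_size,
    classification = config$n_classes,
    regression = 1L
  )
}

#' Build a model with freshly initialized weights
#'
#' Projections use scaled Gaussian initialization (output projections shrunk
#' by `1/sqrt(2 L)` for residual-depth stability); the code embedding
#' codebook is uniform. Every draw flows from `config$seed`.
#'
#' @param config A [model_config()].
#' @return Object of class `retentime_model`: list with `config`, `params`
#'   (nested parameter tree) and `buffers` (batch-norm running statistics).
#' @export
build_model <- function(config) {
  rt_check(inherits(config, "model_config"), "`config` must be a model_config",
           "config_error")
  d <- config$d_model
  gaus <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
  out_sd <- 0.2 / sqrt(2 * config$L)
  with_local_seed(config$seed, {
    params <- list()
    if (config$mode == "continuous") {
      if (config$use_subsampling) {
        params$tok <- tokenizer_weights(config$n_channels, d, model_tok_config(config),
                                        seed = sample.int(1e6, 1))
        params$proj <- list(W = gaus(d, d, 1 / sqrt(d)), b = numeric(d))
      } else {
        params$inproj <- list(W = gaus(config$n_channels, d, 1 / sqrt(config$n_channels)),
                              b = numeric(d))
      }
    } else {
      params$codebook <- matrix(stats::runif(config$vocab_size * d, -0.1, 0.1),
                                config$vocab_size, d)
    }
    params$sos <- stats::rnorm(d, sd = 0.02)
    if (!config$use_rope) {
      params$abspos <- matrix(stats::rnorm(config$max_positions * d, sd = 0.02),
                              config$max_positions, d)
    }
    tc_cfg <- model_tc_config(config)
    params$layers <- lapply(seq_len(config$L), function(i) {
      lw <- list(
        ln1 = list(g = rep(1, d), b = numeric(d)),
        ret = list(W_Q = gaus(d, d, 1 / sqrt(d)),
                   W_K = gaus(d, d, 1 / sqrt(d)),
                   W_V = gaus(d, d, 1 / sqrt(d)),
                   W_O = gaus(d, d, out_sd))
      )
      if (config$gated_output) lw$ret$W_G <- gaus(d, d, 1 / sqrt(d))
      if (config$use_temporal_conv) {
        lw$tc <- temporal_conv_weights(d, tc_cfg, seed = sample.int(1e6, 1))
        # shrink the residual branch output
        if (!is.null(lw$tc$pw)) lw$tc$pw$W <- lw$tc$pw$W * (out_sd * sqrt(d))
      }
      if (config$use_ffn) {
        lw$ln2 <- list(g = rep(1, d), b = numeric(d))
        lw$ffn <- list(W1 = gaus(d, config$d_ff, 1 / sqrt(d)), b1 = numeric(config$d_ff),
                       W2 = gaus(config$d_ff, d, out_sd), b2 = numeric(d))
      }
      lw
    })
    params$lnf <- list(g = rep(1, d), b = numeric(d))
    params$head <- list(W = gaus(d, head_out_dim(config), 1 / sqrt(d)),
                        b = numeric(head_out_dim(config)))
    buffers <- list(layers = lapply(seq_len(config$L), function(i) {
      if (config$use_temporal_conv) list(tc = temporal_conv_buffers(d, tc_cfg))
      else list()
    }))
    structure(list(config = config, params = params, buffers = buffers,
                   train_length = NA_real_),
              class = "retentime_model")
  })
}

#' Number of parameters implied by a configuration
#'
#' Deterministic closed-form count; [build_model()] is asserted against it.
#'
#' @param config A [model_config()].
#' @return Integer parameter count.
#' @export
param_count <- function(config) {
  d <- config$d_model
  n <- 0L
  if (config$mode == "continuous") {
    if (config$use_subsampling) {
      k <- 3L; c1 <- d %/% 2L
      n <- n + k * config$n_channels * c1 + c1 + k * c1 * d + d  # tokenizer
      n <- n + d * d + d                                          # projection
    } else {
      n <- n + config$n_channels * d + d
    }
  } else {
    n <- n + config$vocab_size * d
  }
  n <- n + d                                                      # [SOS]
  if (!config$use_rope) n <- n + config$max_positions * d         # learned positions
  per_layer <- 2L * d + 3L * d * d + d * d                        # ln1 + QKV + O
  if (config$gated_output) per_layer <- per_layer + d * d
  if (config$use_temporal_conv) {
    cfgn <- config$tc_configuration
    if (cfgn != "off") {
      per_layer <- per_layer + 2L * d                              # block LN
      if (cfgn %in% c("DW+PW", "PW+DW+PW", "DW"))
        per_layer <- per_layer + config$tc_kernel * d + d + 2L * d # DW + BN affine
      if (cfgn == "PW+DW+PW") per_layer <- per_layer + d * d + d
      if (cfgn %in% c("DW+PW", "PW+DW+PW", "PW"))
        per_layer <- per_layer + d * d + d
    }
  }
  if (config$use_ffn) per_layer <- per_layer + 2L * d + d * config$d_ff +
    config$d_ff + config$d_ff * d + d
  n <- n + config$L * per_layer
  n <- n + 2L * d                                                 # final LN
  n + d * head_out_dim(config) + head_out_dim(config)             # head
}

# ---- input embedding --------------------------------------------------------

# Returns list(X [(N+1) x d incl SOS], times [N+1], cache, n_raw).
embed_fwd <- function(raw, config, params) {
  d <- config$d_model
  cache <- list(mode = config$mode)
  if (config$mode == "continuous") {
    x <- if (inherits(raw, "timeseries_batch")) raw$series[[1L]] else raw
    rt_check(is.matrix(x), "continuous input must be a T x V matrix or timeseries_batch",
             "config_error")
    rt_check(ncol(x) == config$n_channels,
             sprintf("input has %d channels; model expects %d", ncol(x), config$n_channels),
             "config_error")
    if (config$use_subsampling) {
      tokf <- conv_tokenize_fwd(x, model_tok_config(config), params$tok)
      cache$tok <- tokf
      cache$proj_in <- tokf$y
      emb <- linear_fwd(tokf$y, params$proj$W, params$proj$b)
    } else {
      cache$proj_in <- x
      emb <- linear_fwd(x, params$inproj$W, params$inproj$b)
    }
    n <- nrow(emb)
    times <- c(-1, seq_len(n) - 1)   # ordinal token grid; [SOS] precedes token 0
  } else {
    rt_check(inherits(raw, "event_sequence"), "discrete input must be an event_sequence",
             "config_error")
    codes <- raw$codes
    rt_check(all(codes >= 1L & codes <= config$vocab_size),
             "event codes out of vocabulary range", "config_error")
    cache$codes <- codes
    emb <- params$codebook[codes, , drop = FALSE]
    times <- c(raw$times[1L] - 1, raw$times)
  }
  X <- rbind(params$sos, emb)
  if (!config$use_rope) {
    # learned absolute positions: rows past the trained range stay at their
    # random initialization, which is what breaks length extrapolation
    n <- nrow(X)
    rt_check(n <= nrow(params$abspos),
             sprintf("sequence of %d tokens exceeds max_positions = %d", n,
                     nrow(params$abspos)),
             "config_error")
    X <- X + params$abspos[seq_len(n), , drop = FALSE]
    cache$n_abspos <- n
  }
  list(X = X, times = times, cache = cache, n_tokens = nrow(X))
}

embed_bwd <- function(dX, cache, config, params) {
  grads <- list()
  if (!config$use_rope) {
    dab <- matrix(0, nrow(params$abspos), config$d_model)
    dab[seq_len(cache$n_abspos), ] <- dX
    grads$abspos <- dab
  }
  dsos <- dX[1L, ]
  demb <- dX[-1L, , drop = FALSE]
  if (config$mode == "continuous") {
    if (config$use_subsampling) {
      lb <- linear_bwd(demb, cache$proj_in, params$proj$W)
      grads$proj <- list(W = lb$dW, b = lb$db)
      tb <- conv_tokenize_bwd(lb$dx, cache$tok, params$tok)
      grads$tok <- tb$grads
    } else {
      lb <- linear_bwd(demb, cache$proj_in, params$inproj$W)
      grads$inproj <- list(W = lb$dW, b = lb$db)
    }
  } else {
    dcb <- matrix(0, config$vocab_size, config$d_model)
    for (i in seq_along(cache$codes)) {
      ci <- cache$codes[i]
      dcb[ci, ] <- dcb[ci, ] + demb[i, ]
    }
    grads$codebook <- dcb
  }
  grads$sos <- dsos
  grads
}

#' Embed raw input into the token sequence
#'
#' Continuous input runs through the convolution-subsampling tokenizer and a
#' projection (token times on the subsampled ordinal grid); discrete input is
#' a codebook lookup (token times are the event timestamps). A learned `[SOS]`
#' vector is prepended with a time preceding the first observation.
#'
#' @param raw A `T x V` matrix / [timeseries_batch()] (continuous mode) or an
#'   [event_sequence()] (discrete mode).
#' @param config A [model_config()].
#' @param params Model parameter tree (`model$params`).
#' @return List with `X` (`(N+1) x d` embedding including `[SOS]`) and
#'   `token_times` (length `N+1`, non-decreasing).
#' @export
embed_input <- function(raw, config, params) {
  e <- embed_fwd(raw, config, params)
  list(X = e$X, token_times = e$times)
}

# ---- retention sublayer with cache (parallel form, differentiable) ----------

ret_fwd <- function(Xin, rw, config, times, rot_pos = NULL) {
  d <- config$d_model; nh <- config$n_heads; dh <- config$d_head
  n <- nrow(Xin)
  gam <- model_gammas(config)
  angles <- rotation_angles(dh, config$rotation_base)
  rot_pos <- rot_pos %||% times
  Q <- Xin %*% rw$W_Q
  K <- Xin %*% rw$W_K
  V <- Xin %*% rw$W_V
  O <- matrix(0, n, d)
  hc <- vector("list", nh)
  for (h in seq_len(nh)) {
    cols <- head_cols(h, dh)
    qh <- apply_rotation(Q[, cols, drop = FALSE], rot_pos, angles)
    kh <- apply_rotation(K[, cols, drop = FALSE], rot_pos, angles)
    vh <- V[, cols, drop = FALSE]
    D <- decay_matrix(times, gam[h])
    A <- (qh %*% t(kh)) * D
    rs <- if (config$normalize) rowSums(D) else rep(1, n)
    if (config$normalize) A <- A / rs
    O[, cols] <- A %*% vh
    hc[[h]] <- list(qh = qh, kh = kh, vh = vh, D = D, rs = rs, A = A)
  }
  cache <- list(heads = hc, Xin = Xin, angles = angles, rot_pos = rot_pos)
  if (config$normalize) {
    gn <- group_norm_fwd(O, nh)
    cache$gn <- gn
    O <- gn$y
  }
  if (config$gated_output) {
    gpre <- Xin %*% rw$W_G
    cache$gpre <- gpre
    cache$O_pregate <- O
    O <- O * swish(gpre)
  }
  cache$O_preproj <- O
  list(y = O %*% rw$W_O, cache = cache)
}

ret_bwd <- function(dy, cache, rw, config) {
  nh <- config$n_heads; dh <- config$d_head
  grads <- list(W_O = t(cache$O_preproj) %*% dy)
  dO <- dy %*% t(rw$W_O)
  dXin <- matrix(0, nrow(dO), ncol(dO))
  if (config$gated_output) {
    g <- swish(cache$gpre)
    dgpre <- dO * cache$O_pregate * swish_grad(cache$gpre)
    grads$W_G <- t(cache$Xin) %*% dgpre
    dXin <- dXin + dgpre %*% t(rw$W_G)
    dO <- dO * g
  }
  if (config$normalize) dO <- group_norm_bwd(dO, cache$gn)
  dQ <- matrix(0, nrow(dO), ncol(dO))
  dK <- matrix(0, nrow(dO), ncol(dO))
  dV <- matrix(0, nrow(dO), ncol(dO))
  neg_times <- -cache$rot_pos
  for (h in seq_len(nh)) {
    cols <- head_cols(h, dh)
    ch <- cache$heads[[h]]
    dOh <- dO[, cols, drop = FALSE]
    dA <- dOh %*% t(ch$vh)
    dV[, cols] <- t(ch$A) %*% dOh
    if (config$normalize) dA <- dA / ch$rs
    dQK <- dA * ch$D
    dqh <- dQK %*% ch$kh
    dkh <- t(dQK) %*% ch$qh
    # rotation is orthogonal: transpose = rotation by the negated positions
    dQ[, cols] <- apply_rotation(dqh, neg_times, cache$angles)
    dK[, cols] <- apply_rotation(dkh, neg_times, cache$angles)
  }
  grads$W_Q <- t(cache$Xin) %*% dQ
  grads$W_K <- t(cache$Xin) %*% dK
  grads$W_V <- t(cache$Xin) %*% dV
  dXin <- dXin + dQ %*% t(rw$W_Q) + dK %*% t(rw$W_K) + dV %*% t(rw$W_V)
  list(dx = dXin, grads = grads)
}

# Causal softmax attention with cache (the no-rotary ablation path).
attn_fwd <- function(Xin, rw, config) {
  nh <- config$n_heads; dh <- config$d_head
  n <- nrow(Xin)
  Q <- Xin %*% rw$W_Q
  K <- Xin %*% rw$W_K
  V <- Xin %*% rw$W_V
  O <- matrix(0, n, config$d_model)
  hc <- vector("list", nh)
  for (h in seq_len(nh)) {
    cols <- head_cols(h, dh)
    s <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) / sqrt(dh)
    s[upper.tri(s)] <- -Inf
    P <- softmax_rows(s)
    O[, cols] <- P %*% V[, cols, drop = FALSE]
    hc[[h]] <- list(P = P, qh = Q[, cols, drop = FALSE],
                    kh = K[, cols, drop = FALSE], vh = V[, cols, drop = FALSE])
  }
  cache <- list(heads = hc, Xin = Xin, O_preproj = O)
  list(y = O %*% rw$W_O, cache = cache)
}

attn_bwd <- function(dy, cache, rw, config) {
  nh <- config$n_heads; dh <- config$d_head
  grads <- list(W_O = t(cache$O_preproj) %*% dy)
  dO <- dy %*% t(rw$W_O)
  dQ <- matrix(0, nrow(dO), ncol(dO))
  dK <- matrix(0, nrow(dO), ncol(dO))
  dV <- matrix(0, nrow(dO), ncol(dO))
  for (h in seq_len(nh)) {
    cols <- head_cols(h, dh)
    ch <- cache$heads[[h]]
    dOh <- dO[, cols, drop = FALSE]
    dP <- dOh %*% t(ch$vh)
    dV[, cols] <- t(ch$P) %*% dOh
    ds <- ch$P * (dP - rowSums(dP * ch$P))
    ds <- ds / sqrt(dh)
    dQ[, cols] <- ds %*% ch$kh
    dK[, cols] <- t(ds) %*% ch$qh
  }
  grads$W_Q <- t(cache$Xin) %*% dQ
  grads$W_K <- t(cache$Xin) %*% dK
  grads$W_V <- t(cache$Xin) %*% dV
  dXin <- dQ %*% t(rw$W_Q) + dK %*% t(rw$W_K) + dV %*% t(rw$W_V)
  list(dx = dXin, grads = grads)
}

# ---- decoder layer ----------------------------------------------------------

layer_fwd <- function(H, times, lw, lbuf, config, training = FALSE,
                      form = NULL) {
  cache <- list()
  rot_pos <- if (config$mode == "discrete" && !config$rotate_by_time)
    seq_len(nrow(H)) - 1 else times
  ln1 <- layer_norm_fwd(H, lw$ln1$g, lw$ln1$b)
  cache$ln1 <- ln1
  if (config$use_rope) {
    form <- form %||% "parallel"
    if (training || form == "parallel") {
      mix <- ret_fwd(ln1$y, lw$ret, config, times, rot_pos)
      cache$mix <- mix$cache
      mixed <- mix$y
    } else {
      # non-differentiable dispatch for recurrent/chunk-wise forward passes
      gam <- model_gammas(config)
      angles <- rotation_angles(config$d_head, config$rotation_base)
      O <- if (form == "recurrent") {
        retention_recurrent(ln1$y, lw$ret, angles, gam, times,
                            normalize = config$normalize, rot_positions = rot_pos)
      } else {
        retention_chunkwise(ln1$y, lw$ret, angles, gam, times,
                            chunk_size = config$chunk_size,
                            normalize = config$normalize, rot_positions = rot_pos)
      }
      if (config$normalize) O <- group_norm_heads(O, config$n_heads)
      if (config$gated_output) O <- O * swish(ln1$y %*% lw$ret$W_G)
      mixed <- O %*% lw$ret$W_O
    }
  } else {
    mix <- attn_fwd(ln1$y, lw$ret, config)
    cache$mix <- mix$cache
    mixed <- mix$y
  }
  H2 <- H + mixed
  cache$H2 <- H2
  if (config$use_temporal_conv) {
    tcf <- tc_block_fwd(H2, model_tc_config(config), lw$tc, lbuf$tc,
                        training = training)
    cache$tc <- tcf$cache
    lbuf$tc <- tcf$buffers
    H3 <- tcf$y
  } else {
    H3 <- H2
  }
  if (config$use_ffn) {
    ln2 <- layer_norm_fwd(H3, lw$ln2$g, lw$ln2$b)
    cache$ln2 <- ln2
    f1 <- linear_fwd(ln2$y, lw$ffn$W1, lw$ffn$b1)
    sw <- swish_fwd(f1)
    cache$ffn <- list(in1 = ln2$y, sw = sw)
    H4 <- H3 + linear_fwd(sw$y, lw$ffn$W2, lw$ffn$b2)
  } else {
    H4 <- H3
  }
  list(y = H4, cache = cache, buffers = lbuf)
}

layer_bwd <- function(dy, cache, lw, config) {
  grads <- list()
  if (config$use_ffn) {
    l2 <- linear_bwd(dy, cache$ffn$sw$y, lw$ffn$W2)
    dsw <- swish_bwd(l2$dx, cache$ffn$sw)
    l1 <- linear_bwd(dsw, cache$ffn$in1, lw$ffn$W1)
    grads$ffn <- list(W1 = l1$dW, b1 = l1$db, W2 = l2$dW, b2 = l2$db)
    lnb <- layer_norm_bwd(l1$dx, cache$ln2, lw$ln2$g)
    grads$ln2 <- list(g = lnb$dg, b = lnb$db)
    dH3 <- dy + lnb$dx
  } else {
    dH3 <- dy
  }
  if (config$use_temporal_conv) {
    tb <- tc_block_bwd(dH3, cache$tc, model_tc_config(config), lw$tc)
    grads$tc <- tb$grads
    dH2 <- tb$dx
  } else {
    dH2 <- dH3
  }
  if (config$use_rope) {
    mb <- ret_bwd(dH2, cache$mix, lw$ret, config)
  } else {
    mb <- attn_bwd(dH2, cache$mix, lw$ret, config)
  }
  grads$ret <- mb$grads
  lnb1 <- layer_norm_bwd(mb$dx, cache$ln1, lw$ln1$g)
  grads$ln1 <- list(g = lnb1$dg, b = lnb1$db)
  list(dx = dH2 + lnb1$dx, grads = grads)
}

#' Run one decoder layer
#'
#' Pre-norm residual sublayers: multi-head retention (or causal softmax
#' attention for the no-rotary ablation), temporal convolution block,
#' position-wise feed-forward. Honors every ablation toggle in `config`.
#'
#' @param X Token embedding matrix `N x d`.
#' @param layer_weights One element of `model$params$layers`.
#' @param config A [model_config()].
#' @param times Token positions/timestamps (default ordinal grid).
#' @param buffers Layer buffers (batch-norm running stats); created if NULL.
#' @param training Training-mode flag (batch statistics in batch norm).
#' @return `N x d` output matrix.
#' @export
decoder_layer <- function(X, layer_weights, config, times = NULL,
                          buffers = NULL, training = FALSE) {
  times <- times %||% (seq_len(nrow(X)) - 1)
  buffers <- buffers %||% (if (config$use_temporal_conv)
    list(tc = temporal_conv_buffers(config$d_model, model_tc_config(config)))
    else list())
  layer_fwd(X, times, layer_weights, buffers, config, training = training)$y
}

# ---- full forward -----------------------------------------------------------

# Full model forward. Returns representations (post final layer norm),
# predictions (per-token or pooled by head type), token_times, and caches
# when with_cache = TRUE.
model_forward <- function(model, input, training = FALSE, with_cache = FALSE,
                          form = NULL) {
  config <- model$config
  form <- form %||% config$retention_form
  emb <- embed_fwd(input, config, model$params)
  H <- emb$X
  caches <- if (with_cache) vector("list", config$L)
  for (i in seq_len(config$L)) {
    lf <- layer_fwd(H, emb$times, model$params$layers[[i]],
                    model$buffers$layers[[i]], config,
                    training = training, form = form)
    H <- lf$y
    if (training) model$buffers$layers[[i]] <- lf$buffers
    if (with_cache) caches[[i]] <- lf$cache
  }
  lnf <- layer_norm_fwd(H, model$params$lnf$g, model$params$lnf$b)
  reps <- lnf$y
  if (config$head %in% c("classification", "regression")) {
    pooled <- colMeans(reps)
    predictions <- as.numeric(pooled %*% model$params$head$W + model$params$head$b)
  } else {
    predictions <- linear_fwd(reps, model$params$head$W, model$params$head$b)
  }
  if (anyNA(predictions) || any(!is.finite(predictions))) {
    rt_abort("non-finite values in model output", "numerical_error")
  }
  out <- list(representations = reps, predictions = predictions,
              token_times = emb$times, model = model)
  if (with_cache) {
    out$cache <- list(emb = emb, layers = caches, lnf = lnf, reps = reps)
  }
  out
}

#' Forward pass
#'
#' Stacks the embedded input through all `L` decoder layers and the task
#' head. The forecast head maps each token representation to the next token
#' (a `patch x V` raw-timestep block in continuous mode, vocabulary logits in
#' discrete mode); classification/regression heads act on the average-pooled
#' last-layer representations.
#'
#' @param model A [build_model()] object.
#' @param input Raw input matching `config$mode`.
#' @return List with `representations` (`N x d`), `predictions` and
#'   `token_times`.
#' @export
forward <- function(model, input) {
  out <- model_forward(model, input, training = FALSE)
  out["model"] <- NULL
  out
}

# Backward through a cached forward. dpred matches predictions' shape; for
# pooled heads it is a vector over output units. Returns the gradient tree.
model_backward <- function(model, input, fw, dpred) {
  config <- model$config
  cache <- fw$cache
  reps <- cache$reps
  n <- nrow(reps)
  if (config$head %in% c("classification", "regression")) {
    pooled <- colMeans(reps)
    grads_head <- list(W = outer(pooled, as.numeric(dpred)),
                       b = as.numeric(dpred))
    dpooled <- as.numeric(model$params$head$W %*% dpred)
    dreps <- matrix(dpooled, n, config$d_model, byrow = TRUE) / n
  } else {
    lb <- linear_bwd(dpred, reps, model$params$head$W)
    grads_head <- list(W = lb$dW, b = lb$db)
    dreps <- lb$dx
  }
  lnb <- layer_norm_bwd(dreps, cache$lnf, model$params$lnf$g)
  grads <- list(lnf = list(g = lnb$dg, b = lnb$db), head = grads_head)
  dH <- lnb$dx
  grads$layers <- vector("list", config$L)
  for (i in rev(seq_len(config$L))) {
    lb <- layer_bwd(dH, cache$layers[[i]], model$params$layers[[i]], config)
    grads$layers[[i]] <- lb$grads
    dH <- lb$dx
  }
  emb_grads <- embed_bwd(dH, cache$emb$cache, config, model$params)
  grads[names(emb_grads)] <- emb_grads
  # order grads exactly like params so optimizer trees align
  ordered <- grads[names(model$params)]
  names(ordered) <- names(model$params)
  ordered
}

# ---- checkpointing ----------------------------------------------------------

#' Save a model checkpoint
#'
#' Single-file archive of configuration, parameters, buffers and training
#' metadata; round-trips bit-exactly through [load_checkpoint()].
#'
#' @param model A `retentime_model`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config, params = model$params,
               buffers = model$buffers, train_length = model$train_length,
               package_version = as.character(utils::packageVersion("retentime"))),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return A `retentime_model`.
#' @export
load_checkpoint <- function(path) {
  rt_check(file.exists(path), sprintf("checkpoint not found: %s", path),
           "input_error")
  x <- readRDS(path)
  structure(list(config = x$config, params = x$params, buffers = x$buffers,
                 train_length = x$train_length),
            class = "retentime_model")
}

#' @export
print.retentime_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<retentime_model> %s mode, L=%d d=%d heads=%d (%s form), %d parameters\n",
              cfg$mode, cfg$L, cfg$d_model, cfg$n_heads, cfg$retention_form,
              param_count(cfg)))
  invisible(x)
}
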