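# Multi-head Retention: an attention-free token mixer computing
# (Q K^T ⊙ D) V with a causal exponential-decay mask D, in three equivalent
# computational forms (parallel, recurrent, chunk-wise) plus the
# continuous-time variants for irregular timestamps.

#' Projection weights for retention / attention
#'
#' @param d Model width (square `d x d` projections).
#' @param seed Integer seed for initialization.
#' @param gated Include a swish output-gate projection `W_G`.
#' @param out_proj Include an output projection `W_O`.
#' @param sd Gaussian init standard deviation.
#' @return List of class `projection_weights` with `W_Q`, `W_K`, `W_V` and
#'   optionally `W_G`, `W_O`.
#' @export
projection_weights <- function(d, seed = 1L, gated = FALSE, out_proj = FALSE,
                               sd = 0.2) {
  rt_check(is_count(d, 1L), "`d` must be a positive integer", "config_error")
  with_local_seed(seed, {
    w <- list(
      W_Q = matrix(stats::rnorm(d * d, sd = sd), d, d),
      W_K = matrix(stats::rnorm(d * d, sd = sd), d, d),
      W_V = matrix(stats::rnorm(d * d, sd = sd), d, d)
    )
    if (gated) w$W_G <- matrix(stats::rnorm(d * d, sd = sd), d, d)
    if (out_proj) w$W_O <- matrix(stats::rnorm(d * d, sd = sd), d, d)
    structure(w, class = "projection_weights")
  })
}

#' Retention configuration
#'
#' @param d_model Model width.
#' @param n_heads Number of heads; must divide `d_model`.
#' @param chunk_size Chunk length for the chunk-wise form (default 512).
#' @param form One of `"parallel"`, `"recurrent"`, `"chunkwise"`.
#' @param normalize Apply the retentive-network stabilization: decay-mask rows
#'   are scaled by the reciprocal of their running sum, and head outputs are
#'   group-normalized per position. Off gives the literal unnormalized form.
#' @param gated_output Multiply head outputs by a swish gate of the input.
#' @return Object of class `retention_config`.
#' @export
retention_config <- function(d_model, n_heads, chunk_size = 512L,
                             form = c("parallel", "recurrent", "chunkwise"),
                             normalize = TRUE, gated_output = FALSE) {
  form <- match.arg(form)
  rt_check(is_count(d_model) && is_count(n_heads), "counts must be positive integers",
           "config_error")
  rt_check(d_model %% n_heads == 0L, "`d_model` must be divisible by `n_heads`",
           "config_error")
  d_head <- d_model %/% n_heads
  rt_check(d_head %% 2L == 0L, "head dimension must be even for rotary pairs",
           "config_error")
  rt_check(is_count(chunk_size, 1L), "`chunk_size` must be >= 1", "config_error")
  structure(list(d_model = as.integer(d_model), n_heads = as.integer(n_heads),
                 d_head = as.integer(d_head), chunk_size = as.integer(chunk_size),
                 form = form, normalize = isTRUE(normalize),
                 gated_output = isTRUE(gated_output)),
            class = "retention_config")
}

# Internal: column index range of head h (1-based).
head_cols <- function(h, d_head) ((h - 1L) * d_head + 1L):(h * d_head)

ret_gammas <- function(gammas) {
  if (inherits(gammas, "decay_rates")) gammas$gamma else as.numeric(gammas)
}

ret_positions <- function(timestamps, n) {
  if (is.null(timestamps)) return(seq_len(n) - 1)
  rt_check(length(timestamps) == n, "timestamps length must equal nrow(X)",
           "dimension_error")
  if (n > 1L && any(diff(timestamps) < 0)) {
    rt_abort("timestamps must be non-decreasing", "ordering_error")
  }
  as.numeric(timestamps)
}

#' Parallel-form retention
#'
#' Computes, per head `h`, `O_h = (Q_h K_h^T ⊙ D_h) V_h` where `Q_h`, `K_h`
#' carry rotary position embedding and `D_h` is the head's causal decay mask
#' built from `timestamps` (integer grid `0..N-1` when `timestamps` is NULL).
#' With `normalize = TRUE` each mask row is divided by its sum (running-decay
#' normalization), which is what the recurrent/chunk-wise forms also apply.
#'
#' @param X Input matrix `N x d`.
#' @param weights [projection_weights()] (only `W_Q`, `W_K`, `W_V` are used).
#' @param angles [rotation_angles()] for the head dimension.
#' @param gammas [head_decay_rates()] object or numeric vector, one per head.
#' @param timestamps Optional non-decreasing positions, length `N`.
#' @param normalize Row-sum normalization flag.
#' @param rot_positions Optional positions used for the rotary phase when they
#'   should differ from the decay timestamps (e.g. ordinal-index rotation on
#'   irregular data); defaults to `timestamps`.
#' @return `N x d` output (heads concatenated; no output projection).
#' @export
retention_parallel <- function(X, weights, angles, gammas, timestamps = NULL,
                               normalize = FALSE, rot_positions = NULL) {
  rt_check(is.matrix(X), "`X` must be a matrix", "dimension_error")
  d <- ncol(X); n <- nrow(X)
  gam <- ret_gammas(gammas)
  nh <- length(gam)
  rt_check(d %% nh == 0L, "ncol(X) must be divisible by number of heads",
           "dimension_error")
  dh <- d %/% nh
  rt_check(angles$d_head == dh, "angles d_head must equal per-head width",
           "dimension_error")
  pos <- ret_positions(timestamps, n)
  rpos <- if (is.null(rot_positions)) pos else as.numeric(rot_positions)
  Q <- X %*% weights$W_Q
  K <- X %*% weights$W_K
  V <- X %*% weights$W_V
  out <- matrix(0, n, d)
  for (h in seq_len(nh)) {
    cols <- head_cols(h, dh)
    qh <- apply_rotation(Q[, cols, drop = FALSE], rpos, angles)
    kh <- apply_rotation(K[, cols, drop = FALSE], rpos, angles)
    D <- decay_matrix(pos, gam[h])
    A <- (qh %*% t(kh)) * D
    if (normalize) A <- A / rowSums(D)
    out[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  if (anyNA(out)) rt_abort("NaN in retention output", "numerical_error")
  out
}

#' Fresh recurrent retention state
#'
#' All-zero state (`S_0 = 0`) so that the first update yields
#' `S_1 = K_1^T V_1` consistently with the parallel form.
#'
#' @param d_head Per-head width.
#' @return Object of class `retention_state` with fields `S` (`d_head x d_head`),
#'   `r` (running decay-mass normalizer) and `last_timestamp`.
#' @export
retention_state <- function(d_head) {
  structure(list(S = matrix(0, d_head, d_head), r = 0, last_timestamp = NA_real_),
            class = "retention_state")
}

#' One recurrent retention step
#'
#' `S' = gamma^dt * S + k_n^T v_n`, `o_n = q_n S'` (divided by the running
#' decay mass when `normalize = TRUE`). `dt = 1` recovers the integer-grid
#' recurrence; real `dt` gives the continuous-time update. As `dt` grows the
#' previous state is forgotten and `S'` approaches `k_n^T v_n`.
#'
#' @param q_n,k_n,v_n Per-head vectors (already rotated where applicable).
#' @param state A [retention_state()].
#' @param dt Non-negative time gap since the previous observation.
#' @param gamma Head decay rate in (0, 1).
#' @param normalize Divide the output by the running decay mass.
#' @return List with `o` (output vector) and `state` (updated).
#' @export
retention_recurrent_step <- function(q_n, k_n, v_n, state, dt = 1, gamma,
                                     normalize = FALSE) {
  rt_check(is_number(dt) && dt >= 0, "`dt` must be >= 0", "ordering_error")
  g <- pow_decay(gamma, dt)
  S <- g * state$S + outer(as.numeric(k_n), as.numeric(v_n))
  r <- g * state$r + 1
  o <- as.numeric(q_n %*% S)
  if (normalize) o <- o / r
  list(o = o,
       state = structure(list(S = S, r = r, last_timestamp = state$last_timestamp),
                         class = "retention_state"))
}

# Internal: full-sequence recurrent runner over all heads (oracle for the
# form-equivalence suite and the engine behind streaming inference).
retention_recurrent <- function(X, weights, angles, gammas, timestamps = NULL,
                                normalize = FALSE, rot_positions = NULL) {
  d <- ncol(X); n <- nrow(X)
  gam <- ret_gammas(gammas)
  nh <- length(gam); dh <- d %/% nh
  pos <- ret_positions(timestamps, n)
  rpos <- if (is.null(rot_positions)) pos else as.numeric(rot_positions)
  Q <- X %*% weights$W_Q
  K <- X %*% weights$W_K
  V <- X %*% weights$W_V
  out <- matrix(0, n, d)
  for (h in seq_len(nh)) {
    cols <- head_cols(h, dh)
    qh <- apply_rotation(Q[, cols, drop = FALSE], rpos, angles)
    kh <- apply_rotation(K[, cols, drop = FALSE], rpos, angles)
    vh <- V[, cols, drop = FALSE]
    st <- retention_state(dh)
    for (i in seq_len(n)) {
      dt <- if (i == 1L) 0 else pos[i] - pos[i - 1L]
      step <- retention_recurrent_step(qh[i, ], kh[i, ], vh[i, ], st, dt = dt,
                                       gamma = gam[h], normalize = normalize)
      out[i, cols] <- step$o
      st <- step$state
    }
  }
  out
}

#' Chunk-wise retention
#'
#' Splits the sequence into non-overlapping chunks of `chunk_size`; each chunk
#' is computed in parallel against itself (its own decay mask) plus a carried
#' cross-chunk state decayed by the elapsed time from the previous chunk's
#' last observation. Output equals [retention_parallel()] for every chunk
#' size.
#'
#' @inheritParams retention_parallel
#' @param chunk_size Chunk length (>= 1).
#' @return `N x d` output matrix.
#' @export
retention_chunkwise <- function(X, weights, angles, gammas, timestamps = NULL,
                                chunk_size = 512L, normalize = FALSE,
                                rot_positions = NULL) {
  rt_check(is_count(chunk_size, 1L), "`chunk_size` must be >= 1", "config_error")
  d <- ncol(X); n <- nrow(X)
  gam <- ret_gammas(gammas)
  nh <- length(gam); dh <- d %/% nh
  pos <- ret_positions(timestamps, n)
  rpos <- if (is.null(rot_positions)) pos else as.numeric(rot_positions)
  Q <- X %*% weights$W_Q
  K <- X %*% weights$W_K
  V <- X %*% weights$W_V
  out <- matrix(0, n, d)
  starts <- seq(1L, n, by = chunk_size)
  for (h in seq_len(nh)) {
    cols <- head_cols(h, dh)
    qh <- apply_rotation(Q[, cols, drop = FALSE], rpos, angles)
    kh <- apply_rotation(K[, cols, drop = FALSE], rpos, angles)
    vh <- V[, cols, drop = FALSE]
    S <- matrix(0, dh, dh)   # state referenced at time t_ref
    r <- 0
    t_ref <- NA_real_
    g <- gam[h]
    for (s in starts) {
      idx <- s:min(s + chunk_size - 1L, n)
      tc <- pos[idx]
      qc <- qh[idx, , drop = FALSE]
      kc <- kh[idx, , drop = FALSE]
      vc <- vh[idx, , drop = FALSE]
      Dc <- decay_matrix(tc, g)
      inner <- (qc %*% t(kc)) * Dc
      rows_mass <- rowSums(Dc)
      o <- inner %*% vc
      if (!is.na(t_ref)) {
        cross_decay <- pow_decay(g, tc - t_ref)       # per-row decay to state
        o <- o + (qc %*% S) * cross_decay
        rows_mass <- rows_mass + cross_decay * r
      }
      if (normalize) o <- o / rows_mass
      out[idx, cols] <- o
      # carry state to the chunk's last timestamp
      t_end <- tc[length(tc)]
      w <- pow_decay(g, t_end - tc)                   # decay each kv to t_end
      S_chunk <- t(kc * w) %*% vc
      if (is.na(t_ref)) {
        S <- S_chunk
        r <- sum(w)
      } else {
        gtot <- pow_decay(g, t_end - t_ref)
        S <- gtot * S + S_chunk
        r <- gtot * r + sum(w)
      }
      t_ref <- t_end
    }
  }
  if (anyNA(out)) rt_abort("NaN in retention output", "numerical_error")
  out
}

# Internal: per-position group normalization of each head block (no affine).
group_norm_heads <- function(O, n_heads, eps = 1e-6) {
  d <- ncol(O); dh <- d %/% n_heads
  for (h in seq_len(n_heads)) {
    cols <- head_cols(h, dh)
    blk <- O[, cols, drop = FALSE]
    mu <- rowMeans(blk)
    v <- rowMeans(blk^2) - mu^2
    O[, cols] <- (blk - mu) / sqrt(v + eps)
  }
  O
}

#' Multi-head retention
#'
#' Splits the model width into heads, assigns each head its decay rate from
#' [head_decay_rates()], dispatches to the configured computational form,
#' optionally group-normalizes and gates the head outputs, and applies the
#' output projection when `weights$W_O` is present. All three forms produce
#' the same output (to numerical precision).
#'
#' @param X Input `N x d_model`.
#' @param config A [retention_config()].
#' @param weights [projection_weights()]; `W_G` required when
#'   `config$gated_output`, `W_O` applied if present.
#' @param angles Optional [rotation_angles()]; defaults to the standard
#'   schedule for the head width.
#' @param timestamps Optional real positions (default integer grid).
#' @return `N x d_model` mixed output.
#' @export
multi_head_retention <- function(X, config, weights, angles = NULL,
                                 timestamps = NULL) {
  rt_check(inherits(config, "retention_config"), "`config` must be retention_config",
           "config_error")
  rt_check(ncol(X) == config$d_model, "ncol(X) must equal config$d_model",
           "dimension_error")
  angles <- angles %||% rotation_angles(config$d_head)
  gammas <- head_decay_rates(config$n_heads)
  O <- switch(config$form,
    parallel  = retention_parallel(X, weights, angles, gammas, timestamps,
                                   normalize = config$normalize),
    recurrent = retention_recurrent(X, weights, angles, gammas, timestamps,
                                    normalize = config$normalize),
    chunkwise = retention_chunkwise(X, weights, angles, gammas, timestamps,
                                    chunk_size = config$chunk_size,
                                    normalize = config$normalize)
  )
  if (config$normalize) O <- group_norm_heads(O, config$n_heads)
  if (config$gated_output) {
    rt_check(!is.null(weights$W_G), "gated_output requires weights$W_G",
             "config_error")
    O <- O * swish(X %*% weights$W_G)
  }
  if (!is.null(weights$W_O)) O <- O %*% weights$W_O
  O
}

#' Causal softmax attention
#'
#' The standard masked transformer mixer `softmax(Q K^T / sqrt(d_head)) V`
#' with a lower-triangular causal mask. Used only by the no-rotary (plain
#' GPT-2) ablation; it carries no positional information itself.
#'
#' @param X Input `N x d`.
#' @param weights [projection_weights()]; `W_O` applied if present.
#' @param n_heads Number of heads (default 1).
#' @return `N x d` output.
#' @export
causal_softmax_attention <- function(X, weights, n_heads = 1L) {
  rt_check(is.matrix(X), "`X` must be a matrix", "dimension_error")
  d <- ncol(X); n <- nrow(X)
  rt_check(d %% n_heads == 0L, "ncol(X) must be divisible by n_heads",
           "dimension_error")
  dh <- d %/% n_heads
  Q <- X %*% weights$W_Q
  K <- X %*% weights$W_K
  V <- X %*% weights$W_V
  out <- matrix(0, n, d)
  for (h in seq_len(n_heads)) {
    cols <- head_cols(h, dh)
    s <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) / sqrt(dh)
    s[upper.tri(s)] <- -Inf
    P <- softmax_rows(s)
    out[, cols] <- P %*% V[, cols, drop = FALSE]
  }
  if (!is.null(weights$W_O)) out <- out %*% weights$W_O
  out
}
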