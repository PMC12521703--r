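# Forecasting strategies: trajectory-based autoregressive rollout (recurrent
# state built once over the prompt, then O(1) per emitted step) and
# time-specific direct querying (one decayed-state step at an arbitrary
# future timestamp).

# ---- streaming tokenizer (continuous mode) ----------------------------------

# Initialize the incremental tokenizer from a full prompt: run the two conv
# layers once and keep the receptive-field tails needed to continue.
tok_stream_init <- function(prompt, config, weights) {
  f <- conv_tokenize_fwd(prompt, config, weights)
  v <- ncol(prompt)
  raw_tail <- matrix(0, 2, v)
  nr <- nrow(prompt)
  raw_tail[(3 - min(2, nr)):2, ] <- prompt[(nr - min(2, nr) + 1L):nr, , drop = FALSE]
  c1 <- f$s1$y
  c1_tail <- matrix(0, 2, ncol(c1))
  n1 <- nrow(c1)
  c1_tail[(3 - min(2, n1)):2, ] <- c1[(n1 - min(2, n1) + 1L):n1, , drop = FALSE]
  list(tokens = f$y, raw_tail = raw_tail, raw_count = nr,
       c1_tail = c1_tail, c1_count = n1)
}

# Feed raw rows one at a time; conv layer 1 emits at odd raw indices, layer 2
# at odd layer-1 indices, so each 4 raw timesteps yield exactly one token.
tok_stream_feed <- function(st, rows, weights) {
  new_tokens <- NULL
  k <- dim(weights$W1)[1]
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    st$raw_count <- st$raw_count + 1L
    if (st$raw_count %% 2L == 1L) {
      win <- rbind(st$raw_tail, r)
      pre <- weights$b1
      for (u in seq_len(k)) pre <- pre + win[u, ] %*% matrix(weights$W1[u, , ],
                                                             dim(weights$W1)[2],
                                                             dim(weights$W1)[3])
      c1row <- swish(as.numeric(pre))
      st$c1_count <- st$c1_count + 1L
      if (st$c1_count %% 2L == 1L) {
        winc <- rbind(st$c1_tail, c1row)
        pre2 <- weights$b2
        for (u in seq_len(k)) pre2 <- pre2 + winc[u, ] %*% matrix(weights$W2[u, , ],
                                                                  dim(weights$W2)[2],
                                                                  dim(weights$W2)[3])
        new_tokens <- rbind(new_tokens, swish(as.numeric(pre2)))
      }
      st$c1_tail <- rbind(st$c1_tail[-1L, , drop = FALSE], c1row)
    }
    st$raw_tail <- rbind(st$raw_tail[-1L, , drop = FALSE], r)
  }
  list(state = st, tokens = new_tokens)
}

# ---- streaming model state --------------------------------------------------

ln_row <- function(x, g, b, eps = LN_EPS) {
  mu <- mean(x)
  v <- mean(x^2) - mu^2
  (x - mu) / sqrt(v + eps) * g + b
}

rot_row <- function(x, pos, angles) {
  ang <- pos * angles$theta
  co <- cos(ang); si <- sin(ang)
  odd <- seq(1L, length(x), 2L); even <- odd + 1L
  out <- x
  out[odd] <- x[odd] * co - x[even] * si
  out[even] <- x[odd] * si + x[even] * co
  out
}

#' Initialize a streaming inference state
#'
#' Per layer: one retention state (`S`, decay mass `r`) per head and the
#' temporal-convolution receptive-field tail. The state's size is a function
#' of the configuration only — it does not grow with the consumed sequence,
#' which is what makes per-step inference cost independent of history length.
#'
#' @param model A `retentime_model` (requires `use_rope`).
#' @return Object of class `stream_state`.
#' @export
model_stream_init <- function(model) {
  config <- model$config
  rt_check(config$use_rope,
           "streaming inference requires the rotary-decay model (use_rope)",
           "config_error")
  d <- config$d_model; dh <- config$d_head
  k <- config$tc_kernel
  layers <- lapply(seq_len(config$L), function(i) {
    st <- list(heads = lapply(seq_len(config$n_heads), function(h)
      list(S = matrix(0, dh, dh), r = 0)))
    if (config$use_temporal_conv &&
        config$tc_configuration %in% c("DW+PW", "PW+DW+PW", "DW")) {
      st$tc_tail <- matrix(0, k - 1L, d)
    }
    st
  })
  structure(list(layers = layers, count = 0L, t_ref = NA_real_),
            class = "stream_state")
}

#' Total number of values held in a streaming state
#'
#' @param state A [model_stream_init()] state.
#' @return Integer count (constant in consumed-sequence length).
#' @export
stream_state_size <- function(state) {
  n <- 0L
  for (l in state$layers) {
    for (h in l$heads) n <- n + length(h$S) + 1L
    if (!is.null(l$tc_tail)) n <- n + length(l$tc_tail)
  }
  n + 2L
}

# One token through all layers. x: embedded row (length d). The token's key
# and value are rotated/referenced at time t_k; the query and the state decay
# are evaluated at t_q (t_k == t_q for ordinary consumption; t_q > t_k
# realizes the time-specific query of the last observed event). rot_k/rot_q
# are the rotary positions (equal to t_k/t_q unless ordinal rotation is
# configured). Returns prediction, representation and (when commit) the
# updated state.
model_stream_step <- function(model, state, x, t_k, t_q, rot_k = t_k,
                              rot_q = t_q, commit = TRUE) {
  config <- model$config
  params <- model$params
  gam <- model_gammas(config)
  angles <- rotation_angles(config$d_head, config$rotation_base)
  dh <- config$d_head; nh <- config$n_heads
  dt <- if (state$count == 0L) 0 else t_q - state$t_ref
  rt_check(dt >= 0, "query/step time precedes the current state time",
           "ordering_error")
  h_in <- as.numeric(x)
  for (li in seq_len(config$L)) {
    lw <- params$layers[[li]]
    lst <- state$layers[[li]]
    a <- ln_row(h_in, lw$ln1$g, lw$ln1$b)
    o <- numeric(config$d_model)
    for (h in seq_len(nh)) {
      cols <- head_cols(h, dh)
      q <- rot_row(as.numeric(a %*% lw$ret$W_Q[, cols, drop = FALSE]), rot_q, angles)
      kk <- rot_row(as.numeric(a %*% lw$ret$W_K[, cols, drop = FALSE]), rot_k, angles)
      v <- as.numeric(a %*% lw$ret$W_V[, cols, drop = FALSE])
      g <- pow_decay(gam[h], dt)
      S1 <- g * lst$heads[[h]]$S + outer(kk, v)
      r1 <- g * lst$heads[[h]]$r + 1
      oh <- as.numeric(q %*% S1)
      if (config$normalize) oh <- oh / r1
      o[cols] <- oh
      lst$heads[[h]]$S <- S1
      lst$heads[[h]]$r <- r1
    }
    if (config$normalize) {
      for (h in seq_len(nh)) {
        cols <- head_cols(h, dh)
        blk <- o[cols]
        mu <- mean(blk)
        vv <- mean(blk^2) - mu^2
        o[cols] <- (blk - mu) / sqrt(vv + 1e-6)
      }
    }
    if (config$gated_output) o <- o * swish(as.numeric(a %*% lw$ret$W_G))
    h2 <- h_in + as.numeric(o %*% lw$ret$W_O)
    if (config$use_temporal_conv && config$tc_configuration != "off") {
      tcw <- lw$tc
      cfgn <- config$tc_configuration
      y <- ln_row(h2, tcw$ln$g, tcw$ln$b)
      if (cfgn == "PW+DW+PW") y <- as.numeric(y %*% tcw$pw0$W) + tcw$pw0$b
      if (cfgn %in% c("DW+PW", "PW+DW+PW", "DW")) {
        win <- rbind(lst$tc_tail, y)
        yc <- colSums(win * tcw$dw$W) + tcw$dw$b
        if (config$tc_norm == "batch") {
          bnb <- model$buffers$layers[[li]]$tc$bn
          yc <- (yc - bnb$mean) / sqrt(bnb$var + BN_EPS) * tcw$bn$g + tcw$bn$b
        }
        lst$tc_tail <- rbind(lst$tc_tail[-1L, , drop = FALSE], y)
        y <- swish(yc)
      }
      if (cfgn %in% c("DW+PW", "PW+DW+PW", "PW")) {
        y <- as.numeric(y %*% tcw$pw$W) + tcw$pw$b
        if (cfgn == "PW") y <- swish(y)
      }
      h3 <- h2 + y
    } else {
      h3 <- h2
    }
    if (config$use_ffn) {
      a2 <- ln_row(h3, lw$ln2$g, lw$ln2$b)
      f <- swish(as.numeric(a2 %*% lw$ffn$W1) + lw$ffn$b1)
      h4 <- h3 + as.numeric(f %*% lw$ffn$W2) + lw$ffn$b2
    } else {
      h4 <- h3
    }
    if (commit) state$layers[[li]] <- lst
    h_in <- h4
  }
  rep <- ln_row(h_in, params$lnf$g, params$lnf$b)
  pred <- as.numeric(rep %*% params$head$W) + params$head$b
  if (commit) {
    state$count <- state$count + 1L
    state$t_ref <- t_q
  }
  list(pred = pred, rep = rep, state = state)
}

# Consume an embedded prompt (matrix + times) into a fresh stream state.
stream_consume <- function(model, X, times, rot_pos = NULL) {
  st <- model_stream_init(model)
  rot_pos <- rot_pos %||% times
  last <- NULL
  for (i in seq_len(nrow(X))) {
    last <- model_stream_step(model, st, X[i, ], t_k = times[i], t_q = times[i],
                              rot_k = rot_pos[i], rot_q = rot_pos[i],
                              commit = TRUE)
    st <- last$state
  }
  list(state = st, last = last)
}

#' Forecast result container
#'
#' @param predictions `H x V` matrix (continuous) or NULL.
#' @param rankings List of ranked code vectors per queried time (discrete).
#' @param probabilities Matrix of code probabilities per queried time.
#' @param query_times Times each prediction refers to.
#' @param prompt_length Timesteps (or events) in the prompt.
#' @return Object of class `forecast_result`.
#' @export
forecast_result <- function(predictions = NULL, rankings = NULL,
                            probabilities = NULL, query_times = numeric(),
                            prompt_length = NA_integer_) {
  structure(list(predictions = predictions, rankings = rankings,
                 probabilities = probabilities, query_times = query_times,
                 prompt_length = prompt_length),
            class = "forecast_result")
}

rank_codes <- function(probs) order(probs, decreasing = TRUE)  # ties: code index

# ---- trajectory-based rollout ----------------------------------------------

forecast_trajectory_continuous <- function(model, prompt, horizon) {
  config <- model$config
  x <- if (inherits(prompt, "timeseries_batch")) prompt$series[[1L]] else prompt
  rt_check(is.matrix(x) && nrow(x) >= 1L, "prompt must be a non-empty matrix",
           "input_error")
  v <- ncol(x)
  if (horizon == 0L) {
    return(forecast_result(predictions = matrix(0, 0, v),
                           query_times = numeric(),
                           prompt_length = nrow(x)))
  }
  patch <- config$patch
  n_steps <- ceiling(horizon / patch)
  if (!config$use_rope) {
    # no recurrent form without relative positions: re-encode each step
    cur <- x
    preds <- NULL
    for (s in seq_len(n_steps)) {
      fw <- model_forward(model, cur, training = FALSE)
      p <- fw$predictions
      blk <- matrix(p[nrow(p), ], patch, v, byrow = TRUE)
      preds <- rbind(preds, blk)
      cur <- rbind(cur, blk)
    }
    return(forecast_result(predictions = preds[seq_len(horizon), , drop = FALSE],
                           query_times = nrow(x) + seq_len(horizon),
                           prompt_length = nrow(x)))
  }
  emb <- embed_fwd(x, config, model$params)
  enc <- stream_consume(model, emb$X, emb$times)
  st <- enc$state
  last_pred <- enc$last$pred
  tokst <- if (config$use_subsampling)
    tok_stream_init(x, model_tok_config(config), model$params$tok)
  next_ord <- emb$times[length(emb$times)] + 1
  preds <- NULL
  for (s in seq_len(n_steps)) {
    blk <- matrix(last_pred, patch, v, byrow = TRUE)
    preds <- rbind(preds, blk)
    if (s == n_steps) break
    if (config$use_subsampling) {
      fed <- tok_stream_feed(tokst, blk, model$params$tok)
      tokst <- fed$state
      tok <- fed$tokens[nrow(fed$tokens), ]
      xrow <- as.numeric(tok %*% model$params$proj$W) + model$params$proj$b
    } else {
      xrow <- as.numeric(blk[1L, ] %*% model$params$inproj$W) + model$params$inproj$b
    }
    stp <- model_stream_step(model, st, xrow, t_k = next_ord, t_q = next_ord,
                             commit = TRUE)
    st <- stp$state
    last_pred <- stp$pred
    next_ord <- next_ord + 1
  }
  forecast_result(predictions = preds[seq_len(horizon), , drop = FALSE],
                  query_times = nrow(x) + seq_len(horizon),
                  prompt_length = nrow(x))
}

# Encode events 1..N-1 and hold event N pending (its key/value join the state
# at query time, undecayed relative to the query; see forecast_time_specific).
discrete_encode_pending <- function(model, events) {
  config <- model$config
  emb <- embed_fwd(events, config, model$params)  # rows: SOS, e1..eN
  n <- length(events$codes)
  rot <- if (config$rotate_by_time) emb$times else seq_len(n + 1L) - 1
  keep <- seq_len(n)                              # SOS + events 1..N-1
  enc <- stream_consume(model, emb$X[keep, , drop = FALSE], emb$times[keep],
                        rot[keep])
  list(state = enc$state, x_pend = emb$X[n + 1L, ], t_pend = emb$times[n + 1L],
       rot_pend = rot[n + 1L], rot_next = rot[n + 1L] + 1)
}

# One query of the pending event at time t_q (the continuous-time update:
# state decayed across the full gap, pending key/value added fresh).
discrete_query <- function(model, pend, t_q, commit = FALSE) {
  config <- model$config
  rot_q <- if (config$rotate_by_time) t_q else pend$rot_pend
  stp <- model_stream_step(model, pend$state, pend$x_pend,
                           t_k = if (config$rotate_by_time) pend$t_pend else pend$t_pend,
                           t_q = t_q,
                           rot_k = if (config$rotate_by_time) pend$t_pend else pend$rot_pend,
                           rot_q = rot_q, commit = commit)
  stp
}

#' Trajectory-based forecasting
#'
#' Encodes the prompt once with the recurrent form, then autoregressively
#' rolls out predictions at equal gaps, feeding each prediction back. In
#' continuous mode each token step emits a `patch x V` block of raw
#' timesteps (trimmed to `horizon`); in discrete mode each step emits a
#' ranked code list at the next time point and feeds back the top-ranked
#' (greedy) code. Per-step cost does not depend on how much has been emitted.
#'
#' @param model A trained `retentime_model` with a forecast head.
#' @param prompt `T x V` matrix / [timeseries_batch()] (continuous) or an
#'   [event_sequence()] (discrete).
#' @param horizon Raw timesteps (continuous) or number of future events
#'   (discrete) to predict.
#' @param step Time gap between discrete rollout points (default: median
#'   observed gap in the prompt).
#' @return A [forecast_result()].
#' @export
forecast_trajectory <- function(model, prompt, horizon, step = NULL) {
  rt_check(is_count(horizon, 0L), "`horizon` must be a non-negative integer",
           "input_error")
  config <- model$config
  if (config$mode == "continuous") {
    return(forecast_trajectory_continuous(model, prompt, horizon))
  }
  rt_check(inherits(prompt, "event_sequence"), "discrete prompt must be an event_sequence",
           "input_error")
  n <- length(prompt$codes)
  rt_check(n >= 1L, "prompt must contain at least one event", "input_error")
  if (horizon == 0L) {
    return(forecast_result(rankings = list(), probabilities = NULL,
                           query_times = numeric(), prompt_length = n))
  }
  if (is.null(step)) {
    step <- if (n >= 2L) stats::median(diff(prompt$times)) else 1
    if (!is.finite(step) || step <= 0) step <- 1
  }
  pend <- discrete_encode_pending(model, prompt)
  t_last <- prompt$times[n]
  rankings <- vector("list", horizon)
  probs <- matrix(0, horizon, config$vocab_size)
  for (s in seq_len(horizon)) {
    t_q <- t_last + step
    stp <- discrete_query(model, pend, t_q, commit = TRUE)
    p <- softmax_vec(stp$pred)
    probs[s, ] <- p
    rankings[[s]] <- rank_codes(p)
    best <- rankings[[s]][1L]
    pend <- list(state = stp$state, x_pend = model$params$codebook[best, ],
                 t_pend = t_q, rot_pend = pend$rot_next,
                 rot_next = pend$rot_next + 1)
    t_last <- t_q
  }
  forecast_result(rankings = rankings, probabilities = probs,
                  query_times = prompt$times[n] + step * seq_len(horizon),
                  prompt_length = n)
}

#' Time-specific forecasting
#'
#' Directly predicts at arbitrary future timestamps: the observed events are
#' consumed into the recurrent state; for each query time `t'` the state is
#' decayed across the gap from the second-to-last event, the last event's
#' key/value joins undecayed (so as the gap grows the state converges to
#' `K_N^T V_N`), and the output is read in a single step whose cost is
#' independent of the sequence length.
#'
#' @param model A trained discrete-mode `retentime_model`.
#' @param events An [event_sequence()] of observed history.
#' @param query_times One or more times `>=` the last observed timestamp.
#' @return A [forecast_result()] with one ranking per query time.
#' @export
forecast_time_specific <- function(model, events, query_times) {
  config <- model$config
  rt_check(config$mode == "discrete",
           "time-specific inference applies to discrete event sequences",
           "config_error")
  rt_check(inherits(events, "event_sequence"), "`events` must be an event_sequence",
           "input_error")
  n <- length(events$codes)
  t_last <- events$times[n]
  rt_check(all(query_times >= t_last),
           "query times must not precede the last observed timestamp",
           "ordering_error")
  pend <- discrete_encode_pending(model, events)
  m <- length(query_times)
  rankings <- vector("list", m)
  probs <- matrix(0, m, config$vocab_size)
  for (i in seq_len(m)) {
    stp <- discrete_query(model, pend, query_times[i], commit = FALSE)
    p <- softmax_vec(stp$pred)
    probs[i, ] <- p
    rankings[[i]] <- rank_codes(p)
  }
  forecast_result(rankings = rankings, probabilities = probs,
                  query_times = as.numeric(query_times), prompt_length = n)
}

#' Persistence (last-value) baseline forecast
#'
#' @param prompt `T x V` matrix or [timeseries_batch()].
#' @param horizon Steps to repeat the last observed value.
#' @return `horizon x V` matrix.
#' @export
persistence_forecast <- function(prompt, horizon) {
  x <- if (inherits(prompt, "timeseries_batch")) prompt$series[[1L]] else prompt
  matrix(x[nrow(x), ], horizon, ncol(x), byrow = TRUE)
}

#' Export pooled sequence embeddings
#'
#' Average-pooled final-layer representation per sequence, optionally written
#' to tab-delimited text.
#'
#' @param model A trained model.
#' @param inputs List of sequences matching the model mode.
#' @param path Optional output file.
#' @return `n_sequences x d` matrix.
#' @export
export_embeddings <- function(model, inputs, path = NULL) {
  inputs <- as_sequence_list(inputs, model$config$mode)
  emb <- t(vapply(inputs, function(s) {
    fw <- model_forward(model, s, training = FALSE)
    colMeans(fw$representations)
  }, numeric(model$config$d_model)))
  if (!is.null(path)) {
    utils::write.table(emb, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  emb
}
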