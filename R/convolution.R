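# Convolution-subsampling tokenizer for raw continuous series and the
# depth-wise-separable temporal convolution block used inside each decoder
# layer. All convolutions use causal (left-only) padding so no future
# timestep can leak into a decoder-only next-token model.

#' Tokenizer configuration
#'
#' Two strided 1-D convolution layers (kernel 3, stride 2 by default), each
#' roughly halving the sequence length, so `T` raw timesteps become
#' `N = ceil(ceil(T/2)/2)` tokens — exactly `T/4` when 4 divides `T`.
#'
#' @param kernel_size Convolution kernel width (default 3).
#' @param stride Stride of each layer (default 2).
#' @param n_layers Number of subsampling layers (default 2).
#' @param causal_padding Left-only padding of `kernel_size - 1` (default TRUE).
#' @return Object of class `tokenizer_config`.
#' @export
tokenizer_config <- function(kernel_size = 3L, stride = 2L, n_layers = 2L,
                             causal_padding = TRUE) {
  rt_check(is_count(kernel_size, 1L) && is_count(stride, 1L) && is_count(n_layers, 1L),
           "tokenizer kernel, stride and layers must be positive integers",
           "config_error")
  structure(list(kernel_size = as.integer(kernel_size),
                 stride = as.integer(stride),
                 n_layers = as.integer(n_layers),
                 causal_padding = isTRUE(causal_padding)),
            class = "tokenizer_config")
}

#' Tokenizer output length
#'
#' Applies the per-layer length map `T -> floor((T-1)/stride) + 1` (causal
#' padding, so equals `ceil(T/stride)` for stride 2) `n_layers` times.
#'
#' @param T_in Raw sequence length.
#' @param config A [tokenizer_config()].
#' @return Number of tokens produced.
#' @export
tokenizer_length <- function(T_in, config = tokenizer_config()) {
  n <- T_in
  for (i in seq_len(config$n_layers)) n <- (n - 1L) %/% config$stride + 1L
  as.integer(n)
}

#' Tokenizer weights
#'
#' Channel ramp `V -> d/2 -> d`: the first layer widens the `V` input
#' channels to `d/2`, the second to the token width `d`.
#'
#' @param n_channels Input channel count `V`.
#' @param d Token width.
#' @param config A [tokenizer_config()].
#' @param seed Integer seed.
#' @return Nested list of conv kernels/biases per layer.
#' @export
tokenizer_weights <- function(n_channels, d, config = tokenizer_config(),
                              seed = 1L) {
  rt_check(d %% 2L == 0L, "token width must be even", "config_error")
  k <- config$kernel_size
  c1 <- max(d %/% 2L, 1L)
  with_local_seed(seed, {
    list(
      W1 = array(stats::rnorm(k * n_channels * c1, sd = 1 / sqrt(k * n_channels)),
                 dim = c(k, n_channels, c1)),
      b1 = numeric(c1),
      W2 = array(stats::rnorm(k * c1 * d, sd = 1 / sqrt(k * c1)),
                 dim = c(k, c1, d)),
      b2 = numeric(d)
    )
  })
}

# Internal forward with cache (for backprop through training).
conv_tokenize_fwd <- function(series, config, weights) {
  rt_check(is.matrix(series), "`series` must be a T x V matrix", "dimension_error")
  rt_check(nrow(series) >= 4L, "input too short: need at least 4 timesteps",
           "input_error")
  c1f <- conv1d_fwd(series, weights$W1, weights$b1, stride = config$stride)
  s1 <- swish_fwd(c1f$y)
  c2f <- conv1d_fwd(s1$y, weights$W2, weights$b2, stride = config$stride)
  s2 <- swish_fwd(c2f$y)
  list(y = s2$y, c1 = c1f, s1 = s1, c2 = c2f, s2 = s2)
}

conv_tokenize_bwd <- function(dy, cache, weights) {
  d2 <- swish_bwd(dy, cache$s2)
  b2 <- conv1d_bwd(d2, cache$c2, weights$W2)
  d1 <- swish_bwd(b2$dx, cache$s1)
  b1 <- conv1d_bwd(d1, cache$c1, weights$W1)
  list(dx = b1$dx,
       grads = list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db))
}

#' Convolution-subsampling tokenizer
#'
#' Condenses a raw `T x V` multivariate series into `N` local-feature tokens
#' with two causal strided convolutions (swish between layers), reducing the
#' time dimension to roughly a quarter.
#'
#' @param series Numeric matrix `T x V` (`T >= 4`).
#' @param config A [tokenizer_config()].
#' @param weights A [tokenizer_weights()] list.
#' @return `N x d` token matrix, `N = tokenizer_length(T, config)`.
#' @export
conv_subsample_tokenize <- function(series, config = tokenizer_config(),
                                    weights) {
  conv_tokenize_fwd(series, config, weights)$y
}

#' Temporal convolution configuration
#'
#' @param kernel_size Odd depth-wise kernel width (default 15, the usual
#'   conformer-style receptive field).
#' @param configuration Sub-block layout: `"DW+PW"` (depth-wise separable,
#'   default), `"PW+DW+PW"`, `"DW"`, `"PW"`, or `"off"` (identity ablation).
#' @param norm `"batch"` for batch normalization after the depth-wise
#'   convolution, `"none"` for a strictly deterministic norm-free block.
#' @return Object of class `temporal_conv_config`.
#' @export
temporal_conv_config <- function(kernel_size = 15L,
                                 configuration = c("DW+PW", "PW+DW+PW", "DW", "PW", "off"),
                                 norm = c("batch", "none")) {
  configuration <- match.arg(configuration)
  norm <- match.arg(norm)
  rt_check(is_count(kernel_size, 1L) && kernel_size %% 2L == 1L,
           "`kernel_size` must be odd and >= 1", "config_error")
  structure(list(kernel_size = as.integer(kernel_size),
                 configuration = configuration, norm = norm),
            class = "temporal_conv_config")
}

#' Temporal convolution block weights
#'
#' @param d Model width.
#' @param config A [temporal_conv_config()].
#' @param seed Integer seed.
#' @return Nested list of block parameters (layer norm, depth-wise kernel,
#'   batch-norm affine, point-wise projection as the configuration requires).
#' @export
temporal_conv_weights <- function(d, config = temporal_conv_config(), seed = 1L) {
  cfgn <- config$configuration
  if (cfgn == "off") return(list())
  k <- config$kernel_size
  with_local_seed(seed, {
    w <- list(ln = list(g = rep(1, d), b = numeric(d)))
    if (cfgn %in% c("DW+PW", "PW+DW+PW", "DW")) {
      w$dw <- list(W = matrix(stats::rnorm(k * d, sd = 1 / sqrt(k)), k, d),
                   b = numeric(d))
      w$bn <- list(g = rep(1, d), b = numeric(d))
    }
    if (cfgn == "PW+DW+PW") {
      w$pw0 <- list(W = matrix(stats::rnorm(d * d, sd = 1 / sqrt(d)), d, d),
                    b = numeric(d))
    }
    if (cfgn %in% c("DW+PW", "PW+DW+PW", "PW")) {
      w$pw <- list(W = matrix(stats::rnorm(d * d, sd = 1 / sqrt(d)), d, d),
                   b = numeric(d))
    }
    w
  })
}

temporal_conv_buffers <- function(d, config) {
  if (config$configuration %in% c("DW+PW", "PW+DW+PW", "DW")) {
    list(bn = list(mean = numeric(d), var = rep(1, d)))
  } else {
    list()
  }
}

# Internal forward with cache. Layout (default DW+PW):
# layer norm -> depth-wise conv (causal) -> batch norm -> swish -> point-wise
# conv -> residual add. Other configurations drop or add the marked pieces.
tc_block_fwd <- function(X, config, weights, buffers, training = FALSE) {
  cfgn <- config$configuration
  if (cfgn == "off") {
    return(list(y = X, cfgn = "off", buffers = buffers))
  }
  cache <- list(cfgn = cfgn)
  ln <- layer_norm_fwd(X, weights$ln$g, weights$ln$b)
  cache$ln <- ln
  h <- ln$y
  if (cfgn == "PW+DW+PW") {
    cache$pw0_in <- h
    h <- linear_fwd(h, weights$pw0$W, weights$pw0$b)
  }
  if (cfgn %in% c("DW+PW", "PW+DW+PW", "DW")) {
    dw <- dwconv_fwd(h, weights$dw$W, weights$dw$b)
    cache$dw <- dw
    h <- dw$y
    if (config$norm == "batch") {
      bn <- batch_norm_fwd(h, weights$bn$g, weights$bn$b, buffers$bn, training)
      buffers$bn <- bn$running
      cache$bn <- bn
      h <- bn$y
    }
    sw <- swish_fwd(h)
    cache$sw <- sw
    h <- sw$y
  }
  if (cfgn %in% c("DW+PW", "PW+DW+PW", "PW")) {
    cache$pw_in <- h
    h <- linear_fwd(h, weights$pw$W, weights$pw$b)
    if (cfgn == "PW") {
      sw <- swish_fwd(h)
      cache$swp <- sw
      h <- sw$y
    }
  }
  list(y = X + h, cache = cache, buffers = buffers)
}

tc_block_bwd <- function(dy, cache, config, weights) {
  cfgn <- cache$cfgn
  if (cfgn == "off") return(list(dx = dy, grads = list()))
  grads <- list()
  dh <- dy  # gradient flowing through the conv branch; residual adds dy at the end
  if (cfgn %in% c("DW+PW", "PW+DW+PW", "PW")) {
    if (cfgn == "PW") dh <- swish_bwd(dh, cache$swp)
    lb <- linear_bwd(dh, cache$pw_in, weights$pw$W)
    grads$pw <- list(W = lb$dW, b = lb$db)
    dh <- lb$dx
  }
  if (cfgn %in% c("DW+PW", "PW+DW+PW", "DW")) {
    dh <- swish_bwd(dh, cache$sw)
    if (!is.null(cache$bn)) {
      bb <- batch_norm_bwd(dh, cache$bn, weights$bn$g)
      grads$bn <- list(g = bb$dg, b = bb$db)
      dh <- bb$dx
    }
    db <- dwconv_bwd(dh, cache$dw, weights$dw$W)
    grads$dw <- list(W = db$dW, b = db$db)
    dh <- db$dx
  }
  if (cfgn == "PW+DW+PW") {
    lb <- linear_bwd(dh, cache$pw0_in, weights$pw0$W)
    grads$pw0 <- list(W = lb$dW, b = lb$db)
    dh <- lb$dx
  }
  lnb <- layer_norm_bwd(dh, cache$ln, weights$ln$g)
  grads$ln <- list(g = lnb$dg, b = lnb$db)
  list(dx = dy + lnb$dx, grads = grads)
}

#' Temporal convolution block
#'
#' Depth-wise-separable convolution sublayer capturing local temporal
#' interactions: layer norm, causal depth-wise convolution, batch norm, swish,
#' point-wise convolution, residual add. Output shape equals input shape; the
#' `"off"` configuration is the identity.
#'
#' @param X Input matrix `N x d`.
#' @param config A [temporal_conv_config()].
#' @param weights A [temporal_conv_weights()] list.
#' @param buffers Batch-norm running statistics (created internally if NULL).
#' @param training Use batch statistics (TRUE) or running statistics (FALSE).
#' @return `N x d` output matrix.
#' @export
temporal_conv_block <- function(X, config = temporal_conv_config(), weights,
                                buffers = NULL, training = FALSE) {
  rt_check(is.matrix(X), "`X` must be a matrix", "dimension_error")
  buffers <- buffers %||% temporal_conv_buffers(ncol(X), config)
  tc_block_fwd(X, config, weights, buffers, training = training)$y
}

#' Parameter count of the depth-wise separable block
#'
#' The depth-wise kernel contributes `kernel_size * d + d` parameters (linear
#' in `d`); only the point-wise projection is quadratic.
#'
#' @param weights A [temporal_conv_weights()] list.
#' @return Named vector of parameter counts per component.
#' @export
temporal_conv_param_counts <- function(weights) {
  vapply(weights, function(w) sum(vapply(w, length, 1L)), 1L)
}
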