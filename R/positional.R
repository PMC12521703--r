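# Extrapolatable (xPos) positional machinery: rotary angles applied to
# queries/keys, per-head exponential decay rates, and the causal decay mask
# for integer positions or real-valued timestamps.

#' Rotary angle schedule
#'
#' Per-dimension-pair rotation frequencies for rotary position embedding.
#' Pair `i` (of `d_head / 2`) rotates at `theta[i] = base^(-2 i / d_head)`
#' radians per position unit, so early pairs oscillate fast (capturing short
#' periods) and later pairs slowly (long periods and trends).
#'
#' @param d_head Even head dimension.
#' @param base Angle-schedule base (> 1); 10000 is the standard rotary choice.
#' @return An object of class `rotation_angles` with fields `theta` (length
#'   `d_head / 2`), `base`, and `d_head`.
#' @export
rotation_angles <- function(d_head, base = 10000) {
  rt_check(is_count(d_head, 2L) && d_head %% 2L == 0L,
           "`d_head` must be a positive even integer", "config_error")
  rt_check(is_number(base) && base > 1, "`base` must be > 1", "config_error")
  i <- seq_len(d_head / 2L) - 1L
  structure(
    list(theta = base^(-2 * i / d_head), base = base, d_head = as.integer(d_head)),
    class = "rotation_angles"
  )
}

#' Apply rotary position embedding
#'
#' Rotates each adjacent dimension pair `(2i-1, 2i)` of row `n` by
#' `positions[n] * theta[i]`. Positions may be integer token indices or real
#' timestamps; row norms are preserved (the map is orthogonal per row).
#'
#' @param x Numeric matrix `N x d_head`.
#' @param positions Numeric vector of length `N`.
#' @param angles A [rotation_angles()] object matching `ncol(x)`.
#' @return Rotated matrix, same shape as `x`.
#' @export
apply_rotation <- function(x, positions, angles) {
  rt_check(is.matrix(x), "`x` must be a matrix", "dimension_error")
  rt_check(inherits(angles, "rotation_angles"), "`angles` must be rotation_angles",
           "config_error")
  rt_check(ncol(x) == angles$d_head,
           sprintf("ncol(x) = %d does not match angles d_head = %d", ncol(x), angles$d_head),
           "dimension_error")
  rt_check(length(positions) == nrow(x),
           "`positions` length must equal nrow(x)", "dimension_error")
  ang <- outer(as.numeric(positions), angles$theta)  # N x d_head/2
  co <- cos(ang); si <- sin(ang)
  odd <- seq(1L, ncol(x), by = 2L)
  even <- odd + 1L
  x1 <- x[, odd, drop = FALSE]
  x2 <- x[, even, drop = FALSE]
  out <- x
  out[, odd] <- x1 * co - x2 * si
  out[, even] <- x1 * si + x2 * co
  out
}

#' Per-head exponential decay rates
#'
#' Retention assigns each head a distinct decay rate
#' `gamma_h = 1 - 2^(-5 - h)` for head index `h = 0, ..., n_heads - 1`
#' (0-based, the retentive-network convention). Lower heads forget faster;
#' higher heads retain longer-range context.
#'
#' @param n_heads Number of heads (>= 1).
#' @return Object of class `decay_rates` with field `gamma` (length `n_heads`,
#'   each in (0, 1), strictly increasing).
#' @export
head_decay_rates <- function(n_heads) {
  rt_check(is_count(n_heads, 1L), "`n_heads` must be >= 1", "config_error")
  h <- seq_len(n_heads) - 1L
  structure(list(gamma = 1 - 2^(-5 - h)), class = "decay_rates")
}

# Internal: N x N causal decay matrix for sorted timestamps, log-space with
# underflow clamping (exponents below -60 become exactly 0).
decay_matrix <- function(timestamps, gamma) {
  n <- length(timestamps)
  if (n > 1L && any(diff(timestamps) < 0)) {
    rt_abort("timestamps must be non-decreasing", "ordering_error")
  }
  dt <- outer(as.numeric(timestamps), as.numeric(timestamps), "-")  # t_n - t_m
  e <- log(gamma) * dt
  d <- ifelse(e < -60, 0, exp(e))
  d[upper.tri(d)] <- 0
  d
}

#' Causal decay mask
#'
#' Builds the lower-triangular decay matrix `D[n, m] = gamma^(t_n - t_m)` for
#' `n >= m` (0 above the diagonal). On the integer grid `0, 1, ..., N-1` this
#' is the regular retention mask `gamma^(n - m)`; with real timestamps it is
#' the continuous-time mask adapted to the observed time gaps. Computed in log
#' space; exponents below -60 underflow to exact 0.
#'
#' @param positions_or_timestamps Non-decreasing numeric vector, length `N`.
#' @param gamma Decay rate in (0, 1).
#' @return Object of class `decay_mask` with fields `D` (the `N x N` matrix),
#'   `positions` and `gamma`.
#' @export
build_decay_mask <- function(positions_or_timestamps, gamma) {
  rt_check(is_number(gamma) && gamma > 0 && gamma < 1,
           "`gamma` must be in (0, 1)", "config_error")
  rt_check(is.numeric(positions_or_timestamps) && length(positions_or_timestamps) >= 1L,
           "positions must be a non-empty numeric vector", "config_error")
  d <- decay_matrix(positions_or_timestamps, gamma)
  structure(
    list(D = d, positions = as.numeric(positions_or_timestamps), gamma = gamma),
    class = "decay_mask"
  )
}

#' Write a decay mask or angle schedule to delimited text (debug aid)
#'
#' @param x A `decay_mask` or `rotation_angles` object.
#' @param path Output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_positional_debug <- function(x, path) {
  if (inherits(x, "decay_mask")) {
    utils::write.table(x$D, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  } else if (inherits(x, "rotation_angles")) {
    utils::write.table(data.frame(pair = seq_along(x$theta) - 1L, theta = x$theta),
                       path, sep = "\t", row.names = FALSE)
  } else {
    rt_abort("unsupported object for positional debug dump", "config_error")
  }
  invisible(path)
}
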