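# Internal helpers shared across modules.

# Signal a classed error. `class` is the short condition class, e.g.
# "config_error"; the full class is "retentime_<class>".
rt_abort <- function(message, class) {
  stop(structure(
    class = c(paste0("retentime_", class), "retentime_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

rt_check <- function(cond, message, class) {
  if (!isTRUE(cond)) rt_abort(message, class)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Numerically stable logistic.
sigmoid <- function(x) {
  out <- x
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

swish <- function(x) x * sigmoid(x)

# d/dx swish(x)
swish_grad <- function(x) {
  s <- sigmoid(x)
  s + x * s * (1 - s)
}

# Row-wise softmax of a matrix, stable.
softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# gamma^dt computed in log space; exponents below `floor` underflow to 0.
# Vectorised over dt (gamma scalar in (0, 1)).
pow_decay <- function(gamma, dt, floor = -60) {
  e <- log(gamma) * dt
  out <- ifelse(e < floor, 0, exp(e))
  out
}

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Broadcast a length-d vector across the rows of an N x d matrix.
row_broadcast <- function(v, n) matrix(v, nrow = n, ncol = length(v), byrow = TRUE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == as.integer(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
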