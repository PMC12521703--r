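# Synthetic data with the statistical structure the architecture targets:
# trend + periodic multivariate signals, and irregularly-timestamped code
# sequences with age-trend and relapse-period structure.

#' Biosignal generator configuration
#'
#' Each channel `c` is `trend_slopes[c] * t + sum_j amplitudes[[c]][j] *
#' sin(2 pi t / periods[[c]][j]) + N(0, noise_sd)` on the grid
#' `t = 0, ..., length - 1`.
#'
#' @param n_series Number of independent series.
#' @param length Timesteps per series (>= 1).
#' @param n_channels Channels per timestep.
#' @param trend_slopes Per-channel slope (units per timestep); recycled.
#' @param periods Per-channel period(s) in timesteps (list or vector, each
#'   > 1); recycled across channels.
#' @param amplitudes Per-channel amplitude(s) matching `periods`.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param phase_jitter Uniform random phase offset per series/channel in
#'   `[0, 2 pi)` so series are not identical copies (0 disables).
#' @param seed Integer seed; generation is bit-reproducible.
#' @return Object of class `biosignal_gen_config`.
#' @export
biosignal_gen_config <- function(n_series = 1L, length = 512L, n_channels = 1L,
                                 trend_slopes = 0, periods = 64,
                                 amplitudes = 1, noise_sd = 0,
                                 phase_jitter = 0, seed = 1L) {
  rt_check(is_count(n_series) && is_count(length) && is_count(n_channels),
           "series, length and channel counts must be positive integers",
           "config_error")
  per <- if (is.list(periods)) periods else as.list(periods)
  amp <- if (is.list(amplitudes)) amplitudes else as.list(amplitudes)
  per <- rep_len(per, n_channels)
  amp <- rep_len(amp, n_channels)
  for (c in seq_len(n_channels)) {
    rt_check(all(per[[c]] > 1), "all periods must be > 1", "config_error")
    rt_check(length(per[[c]]) == length(amp[[c]]) || length(amp[[c]]) == 1L,
             "amplitudes must match periods per channel", "config_error")
    amp[[c]] <- rep_len(amp[[c]], base::length(per[[c]]))
  }
  rt_check(is_number(noise_sd) && noise_sd >= 0, "`noise_sd` must be >= 0",
           "config_error")
  structure(list(n_series = as.integer(n_series), length = as.integer(length),
                 n_channels = as.integer(n_channels),
                 trend_slopes = rep_len(as.numeric(trend_slopes), n_channels),
                 periods = per, amplitudes = amp,
                 noise_sd = noise_sd, phase_jitter = phase_jitter,
                 seed = as.integer(seed)),
            class = "biosignal_gen_config")
}

#' Continuous multivariate signal container
#'
#' @param series List of `T x V` matrices.
#' @param channels Channel names.
#' @param step Sampling step (time units per timestep).
#' @return Object of class `timeseries_batch`.
#' @export
timeseries_batch <- function(series, channels = NULL, step = 1) {
  rt_check(is.list(series) && all(vapply(series, is.matrix, TRUE)),
           "`series` must be a list of matrices", "config_error")
  v <- ncol(series[[1L]])
  rt_check(all(vapply(series, ncol, 1L) == v), "inconsistent channel counts",
           "config_error")
  channels <- channels %||% paste0("ch", seq_len(v))
  structure(list(series = series, channels = channels, step = step),
            class = "timeseries_batch")
}

#' Generate trend + periodic biosignals
#'
#' @param config A [biosignal_gen_config()].
#' @return A [timeseries_batch()] of `n_series` matrices `length x n_channels`.
#' @export
generate_biosignal <- function(config) {
  rt_check(inherits(config, "biosignal_gen_config"),
           "`config` must be a biosignal_gen_config", "config_error")
  t <- seq_len(config$length) - 1
  with_local_seed(config$seed, {
    series <- lapply(seq_len(config$n_series), function(s) {
      x <- matrix(0, config$length, config$n_channels)
      for (c in seq_len(config$n_channels)) {
        val <- config$trend_slopes[c] * t
        for (j in seq_along(config$periods[[c]])) {
          phase <- if (config$phase_jitter > 0)
            stats::runif(1, 0, 2 * pi) * config$phase_jitter else 0
          val <- val + config$amplitudes[[c]][j] *
            sin(2 * pi * t / config$periods[[c]][j] + phase)
        }
        if (config$noise_sd > 0) {
          val <- val + stats::rnorm(config$length, sd = config$noise_sd)
        }
        x[, c] <- val
      }
      x
    })
    timeseries_batch(series)
  })
}

#' Event-sequence generator configuration
#'
#' Per patient, event times follow homogeneous Poisson arrivals at
#' `base_rate` events per unit time ("days"); at each event the code is drawn
#' from a softmax over per-code log-weights in which `trend_codes` gain
#' weight linearly with time (age-related susceptibility) and
#' `periodic_codes` oscillate with `relapse_period` (exacerbation/recovery
#' cycles).
#'
#' @param n_patients Number of patients.
#' @param vocab_size Code vocabulary size (>= 2).
#' @param mean_events Mean events per patient (>= 2; Poisson, floored at 2).
#' @param base_rate Events per unit time (> 0).
#' @param trend_codes Integer codes whose hazard grows with time.
#' @param periodic_codes Integer codes with relapse-period structure.
#' @param relapse_period Relapse period in time units.
#' @param trend_strength Logit gain of trend codes across the expected
#'   observation span.
#' @param periodic_strength Logit oscillation amplitude of periodic codes.
#' @param seed Integer seed.
#' @return Object of class `event_gen_config`.
#' @export
event_gen_config <- function(n_patients = 100L, vocab_size = 50L,
                             mean_events = 40L, base_rate = 0.1,
                             trend_codes = integer(), periodic_codes = integer(),
                             relapse_period = 90, trend_strength = 3,
                             periodic_strength = 3, seed = 1L) {
  rt_check(is_count(n_patients), "`n_patients` must be a positive integer",
           "config_error")
  rt_check(is_count(vocab_size, 2L), "`vocab_size` must be >= 2", "config_error")
  rt_check(is_count(mean_events, 2L), "`mean_events` must be >= 2", "config_error")
  rt_check(is_number(base_rate) && base_rate > 0, "`base_rate` must be > 0",
           "config_error")
  rt_check(all(trend_codes %in% seq_len(vocab_size)) &&
             all(periodic_codes %in% seq_len(vocab_size)),
           "trend/periodic codes must be within the vocabulary", "config_error")
  structure(list(n_patients = as.integer(n_patients),
                 vocab_size = as.integer(vocab_size),
                 mean_events = as.integer(mean_events), base_rate = base_rate,
                 trend_codes = as.integer(trend_codes),
                 periodic_codes = as.integer(periodic_codes),
                 relapse_period = relapse_period,
                 trend_strength = trend_strength,
                 periodic_strength = periodic_strength,
                 seed = as.integer(seed)),
            class = "event_gen_config")
}

#' One patient's timestamped code sequence
#'
#' @param patient_id Identifier string.
#' @param times Strictly increasing real timestamps (abstract "days").
#' @param codes Integer codes, same length as `times`.
#' @return Object of class `event_sequence`.
#' @export
event_sequence <- function(patient_id, times, codes) {
  rt_check(length(times) == length(codes) && length(times) >= 1L,
           "`times` and `codes` must be equal-length and non-empty",
           "config_error")
  rt_check(all(diff(times) > 0) || length(times) == 1L,
           sprintf("timestamps must be strictly increasing (patient %s)", patient_id),
           "ordering_error")
  structure(list(patient_id = as.character(patient_id),
                 times = as.numeric(times), codes = as.integer(codes)),
            class = "event_sequence")
}

# Code logits at time t under an event generator config.
event_code_logits <- function(config, t, span) {
  logits <- numeric(config$vocab_size)
  if (length(config$trend_codes)) {
    logits[config$trend_codes] <- logits[config$trend_codes] +
      config$trend_strength * (t / span - 0.5)
  }
  if (length(config$periodic_codes)) {
    logits[config$periodic_codes] <- logits[config$periodic_codes] +
      config$periodic_strength * sin(2 * pi * t / config$relapse_period)
  }
  logits
}

#' Generate irregularly-sampled event sequences
#'
#' @param config An [event_gen_config()].
#' @return List of [event_sequence()] objects, one per patient.
#' @export
generate_event_sequences <- function(config) {
  rt_check(inherits(config, "event_gen_config"),
           "`config` must be an event_gen_config", "config_error")
  span <- config$mean_events / config$base_rate   # expected observation span
  with_local_seed(config$seed, {
    lapply(seq_len(config$n_patients), function(p) {
      n_ev <- max(2L, stats::rpois(1, config$mean_events))
      gaps <- stats::rexp(n_ev, rate = config$base_rate)
      gaps <- pmax(gaps, 1e-6)                    # strictly increasing times
      times <- cumsum(gaps)
      codes <- vapply(times, function(t) {
        w <- softmax_vec(event_code_logits(config, t, span))
        sample.int(config$vocab_size, 1L, prob = w)
      }, 1L)
      event_sequence(sprintf("p%04d", p), times, codes)
    })
  })
}

#' Split series into non-overlapping prompt/target forecast windows
#'
#' Each window takes `lookup` timesteps as the prompt and the following
#' `horizon` as the target; consecutive windows do not overlap, giving
#' `floor(T / (lookup + horizon))` pairs per series.
#'
#' @param series A [timeseries_batch()] or a single `T x V` matrix.
#' @param lookup Prompt length (>= 1).
#' @param horizon Target length (>= 1).
#' @return List of `list(prompt, target)` matrix pairs.
#' @export
make_forecast_windows <- function(series, lookup, horizon) {
  rt_check(is_count(lookup, 1L), "`lookup` must be >= 1", "window_error")
  rt_check(is_count(horizon, 1L), "`horizon` must be >= 1", "window_error")
  mats <- if (inherits(series, "timeseries_batch")) series$series else list(series)
  w <- lookup + horizon
  out <- list()
  for (x in mats) {
    rt_check(w <= nrow(x),
             sprintf("lookup + horizon = %d exceeds series length %d", w, nrow(x)),
             "window_error")
    n_win <- nrow(x) %/% w
    for (j in seq_len(n_win)) {
      s <- (j - 1L) * w
      out[[length(out) + 1L]] <- list(
        prompt = x[(s + 1L):(s + lookup), , drop = FALSE],
        target = x[(s + lookup + 1L):(s + w), , drop = FALSE]
      )
    }
  }
  out
}
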