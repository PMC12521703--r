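# Task metrics (MAE, top-K recall, multi-label AUPRC) and experiment
# harnesses (extrapolation sweep with a persistence comparator).

#' Mean absolute error
#'
#' @param pred,truth Numeric matrices/vectors of equal shape.
#' @return Mean of absolute elementwise differences.
#' @export
mae <- function(pred, truth) {
  rt_check(length(pred) == length(truth) &&
             identical(dim(pred) %||% length(pred), dim(truth) %||% length(truth)),
           "`pred` and `truth` must have equal shape", "dimension_error")
  mean(abs(pred - truth))
}

#' Top-K recall
#'
#' Fraction of ground-truth codes found within the model's K highest-ranked
#' predictions at the corresponding target, averaged over targets within a
#' patient and then over patients, reported as a percentage.
#'
#' @param rankings Ranked code vectors: a list (one per target) or a list of
#'   such lists (one per patient).
#' @param truths True codes aligned with `rankings` (vector, or list of
#'   vectors per patient).
#' @param K Ranking depth (>= 1).
#' @return Recall percentage in `[0, 100]`.
#' @export
top_k_recall <- function(rankings, truths, K) {
  rt_check(is_count(K, 1L), "`K` must be >= 1", "config_error")
  per_patient <- is.list(truths)
  if (!per_patient) {
    rankings <- list(rankings)
    truths <- list(truths)
  }
  rt_check(length(rankings) == length(truths),
           "`rankings` and `truths` must align", "dimension_error")
  total <- sum(vapply(truths, length, 1L))
  rt_check(total > 0L, "no ground-truth codes to score", "metric_error")
  pp <- mapply(function(rk, tr) {
    rt_check(length(rk) == length(tr), "rankings/truths length mismatch per patient",
             "dimension_error")
    hits <- mapply(function(r, t) t %in% r[seq_len(min(K, length(r)))], rk, tr)
    mean(hits)
  }, rankings, truths)
  100 * mean(pp)
}

# Average precision for one label via the step-wise (threshold) integral:
# AP = sum over distinct score thresholds of (R_i - R_{i-1}) * P_i.
average_precision <- function(scores, truth) {
  npos <- sum(truth)
  if (npos == 0L) return(NA_real_)
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  r_prev <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(truth[sel])
    prec <- tp / sum(sel)
    rec <- tp / npos
    ap <- ap + (rec - r_prev) * prec
    r_prev <- rec
  }
  ap
}

#' Multi-label area under the precision-recall curve
#'
#' Step-wise (non-interpolated) threshold integral per label; labels with no
#' positive example are skipped with a warning. Reported in percent.
#'
#' @param scores `n x labels` score matrix.
#' @param truths Binary matrix of the same shape.
#' @return List with `per_label` (percent, NA for skipped labels) and `mean`.
#' @export
auprc_multilabel <- function(scores, truths) {
  rt_check(is.matrix(scores) && all(dim(scores) == dim(truths)),
           "`scores` and `truths` must be matrices of equal shape",
           "dimension_error")
  per <- vapply(seq_len(ncol(scores)), function(j)
    average_precision(scores[, j], truths[, j] != 0), 1)
  if (anyNA(per)) {
    warning(sprintf("%d label(s) without positives skipped", sum(is.na(per))))
  }
  rt_check(!all(is.na(per)), "no label has a positive example", "metric_error")
  list(per_label = 100 * per, mean = 100 * mean(per, na.rm = TRUE))
}

#' Extrapolation sweep over forecasting horizons
#'
#' For each horizon, cuts non-overlapping (prompt, target) windows with a
#' fixed look-up length, rolls the model out trajectory-style, and reports
#' MAE alongside the persistence (last-value) baseline. Horizons whose
#' prompt + horizon extend past the model's pre-training length are marked
#' as extrapolation.
#'
#' @param model A trained continuous-mode forecast model.
#' @param data A [timeseries_batch()] or list of matrices.
#' @param lookup Prompt length in raw timesteps.
#' @param horizons Integer vector of forecast horizons.
#' @return `data.frame` with columns `horizon`, `mae_model`,
#'   `mae_persistence`, `extrapolation`, `n_windows`.
#' @export
run_extrapolation_sweep <- function(model, data, lookup, horizons) {
  rt_check(length(horizons) >= 1L, "`horizons` must be non-empty", "config_error")
  series <- if (inherits(data, "timeseries_batch")) data
            else timeseries_batch(as_sequence_list(data, "continuous"))
  out <- lapply(horizons, function(h) {
    windows <- make_forecast_windows(series, lookup, h)
    errs_m <- errs_p <- numeric(length(windows))
    for (i in seq_along(windows)) {
      w <- windows[[i]]
      fc <- forecast_trajectory(model, w$prompt, horizon = h)
      errs_m[i] <- mae(fc$predictions, w$target)
      errs_p[i] <- mae(persistence_forecast(w$prompt, h), w$target)
    }
    data.frame(horizon = h, mae_model = mean(errs_m),
               mae_persistence = mean(errs_p),
               extrapolation = !is.na(model$train_length) &&
                 (lookup + h) > model$train_length,
               n_windows = length(windows))
  })
  do.call(rbind, out)
}
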