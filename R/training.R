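# Next-token generative pre-training and downstream fine-tuning. Teacher
# forcing throughout; Adam with linear warmup + cosine decay; gradients are
# exact (hand-derived backward passes), clipped by global norm.

#' Training configuration
#'
#' @param epochs_pretrain Pre-training epochs.
#' @param epochs_finetune Fine-tuning epochs.
#' @param batch_size Sequences per optimizer step (gradient accumulation).
#' @param learning_rate Peak Adam learning rate.
#' @param loss `"mse"` (continuous) or `"cross_entropy"` (discrete).
#' @param task `"forecast"`, `"classification"` or `"regression"`.
#' @param warmup_frac Fraction of steps used for linear warmup.
#' @param clip_norm Global gradient-norm clip (NULL disables).
#' @param seed Seed controlling shuffling (and nothing else).
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs_pretrain = 20L, epochs_finetune = 5L,
                         batch_size = 4L, learning_rate = 3e-3,
                         loss = c("mse", "cross_entropy"),
                         task = c("forecast", "classification", "regression"),
                         warmup_frac = 0.1, clip_norm = 1.0, seed = 1L) {
  loss <- match.arg(loss)
  task <- match.arg(task)
  rt_check(is_count(epochs_pretrain, 1L) && is_count(epochs_finetune, 1L) &&
             is_count(batch_size, 1L),
           "epoch and batch counts must be positive integers", "config_error")
  rt_check(is_number(learning_rate) && learning_rate >= 0,
           "`learning_rate` must be >= 0", "config_error")
  structure(list(epochs_pretrain = as.integer(epochs_pretrain),
                 epochs_finetune = as.integer(epochs_finetune),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, loss = loss, task = task,
                 warmup_frac = warmup_frac, clip_norm = clip_norm,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Normalize training inputs to a plain list of sequences.
as_sequence_list <- function(data, mode) {
  if (inherits(data, "timeseries_batch")) return(data$series)
  if (inherits(data, "event_sequence")) return(list(data))
  if (is.matrix(data)) return(list(data))
  rt_check(is.list(data) && length(data) >= 1L, "`data` must be a non-empty list",
           "config_error")
  data
}

# Next-patch targets for a continuous raw sequence: prediction row j (the
# output of embedding row j, i.e. [SOS] for j = 1) is scored against raw
# patch j. Returns M x (patch * V).
patch_targets <- function(x, patch) {
  m <- nrow(x) %/% patch
  out <- matrix(0, m, patch * ncol(x))
  for (j in seq_len(m)) {
    rows <- ((j - 1L) * patch + 1L):(j * patch)
    out[j, ] <- as.numeric(t(x[rows, , drop = FALSE]))
  }
  out
}

# Loss + gradients for one pre-training sequence (teacher forcing).
pretrain_seq_grads <- function(model, x) {
  config <- model$config
  fw <- model_forward(model, x, training = TRUE, with_cache = TRUE,
                      form = "parallel")
  pred <- fw$predictions
  if (config$mode == "continuous") {
    tgt <- patch_targets(if (inherits(x, "timeseries_batch")) x$series[[1L]] else x,
                         config$patch)
    m <- min(nrow(tgt), nrow(pred) - 1L)
    sub <- mse_loss(pred[seq_len(m), , drop = FALSE], tgt[seq_len(m), , drop = FALSE])
    dpred <- matrix(0, nrow(pred), ncol(pred))
    dpred[seq_len(m), ] <- sub$dpred
    loss <- sub$loss
  } else {
    codes <- x$codes
    n <- length(codes)
    targets <- rep(NA_integer_, nrow(pred))
    targets[seq_len(n)] <- codes          # row 1 ([SOS]) predicts code 1, etc.
    sub <- cross_entropy_loss(pred, targets)
    dpred <- sub$dpred
    loss <- sub$loss
  }
  grads <- model_backward(model, x, fw, dpred)
  list(loss = loss, grads = grads, model = fw$model)
}

#' Next-token generative pre-training
#'
#' Teacher-forced next-token objective: MSE on next raw patches for
#' continuous signals, cross-entropy on next-code logits for discrete event
#' sequences. Deterministic given the seeds in `model$config` and `config`.
#'
#' @param model A [build_model()] model with a forecast head.
#' @param data List of sequences (matrices / a [timeseries_batch()] in
#'   continuous mode; [event_sequence()] objects in discrete mode).
#' @param config A [train_config()].
#' @return List with `model` (trained) and `loss_history` (per-epoch mean
#'   training loss).
#' @export
pretrain_next_token <- function(model, data, config) {
  rt_check(inherits(model, "retentime_model"), "`model` must be a retentime_model",
           "config_error")
  rt_check(model$config$head == "forecast",
           "pre-training requires the forecast head", "config_error")
  seqs <- as_sequence_list(data, model$config$mode)
  if (model$config$mode == "continuous") {
    ok <- vapply(seqs, is.matrix, TRUE)
    rt_check(all(ok), "continuous pre-training data must be matrices", "config_error")
    model$train_length <- max(vapply(seqs, nrow, 1L))
  } else {
    ok <- vapply(seqs, function(s) inherits(s, "event_sequence"), TRUE)
    rt_check(all(ok), "discrete pre-training data must be event_sequence objects",
             "config_error")
    model$train_length <- max(vapply(seqs, function(s) length(s$codes), 1L))
  }
  epochs <- config$epochs_pretrain
  run_training_loop(model, seqs, config, epochs, pretrain_seq_grads,
                    metric_fun = NULL)
}

# Shared epoch/batch loop. grad_fun(model, item) -> list(loss, grads, model,
# metric?). Returns list(model, loss_history, metric_history).
run_training_loop <- function(model, items, config, epochs, grad_fun,
                              metric_fun = NULL) {
  n <- length(items)
  bs <- min(config$batch_size, n)
  steps_per_epoch <- ceiling(n / bs)
  total_steps <- max(1L, epochs * steps_per_epoch)
  opt <- adam_init(model$params)
  loss_history <- numeric(epochs)
  metric_history <- numeric(epochs)
  step <- 0L
  with_local_seed(config$seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_losses <- numeric(0)
      ep_metrics <- numeric(0)
      for (b in seq_len(steps_per_epoch)) {
        idx <- ord[((b - 1L) * bs + 1L):min(b * bs, n)]
        acc <- NULL
        for (i in idx) {
          g <- grad_fun(model, items[[i]])
          if (!is.finite(g$loss)) {
            rt_abort(sprintf("training diverged: non-finite loss at epoch %d", ep),
                     "training_error")
          }
          model <- g$model            # batch-norm running stats advance
          acc <- if (is.null(acc)) g$grads else add_trees(acc, g$grads)
          ep_losses <- c(ep_losses, g$loss)
          if (!is.null(g$metric)) ep_metrics <- c(ep_metrics, g$metric)
        }
        acc <- param_map(function(x) x / length(idx), acc)
        if (!is.null(config$clip_norm)) acc <- clip_grads(acc, config$clip_norm)
        step <- step + 1L
        lr <- lr_schedule(step, total_steps, config$learning_rate,
                          config$warmup_frac)
        if (lr > 0) {
          upd <- adam_step(model$params, acc, opt, lr)
          model$params <- upd$params
          opt <- upd$state
        } else {
          opt$t <- opt$t + 1L
        }
      }
      loss_history[ep] <- mean(ep_losses)
      metric_history[ep] <- if (length(ep_metrics)) mean(ep_metrics) else NA_real_
    }
  })
  list(model = model, loss_history = loss_history,
       metric_history = metric_history)
}

# Loss + gradients for one labeled example during fine-tuning.
finetune_item_grads <- function(model, item, task) {
  fw <- model_forward(model, item$x, training = TRUE, with_cache = TRUE,
                      form = "parallel")
  pred <- fw$predictions
  if (task == "classification") {
    p <- softmax_vec(pred)
    loss <- -log(max(p[item$y], 1e-12))
    dpred <- p
    dpred[item$y] <- dpred[item$y] - 1
    metric <- as.numeric(which.max(pred) == item$y)
  } else if (task == "regression") {
    err <- pred[1L] - item$y
    loss <- err^2
    dpred <- 2 * err
    metric <- abs(err)
  } else { # forecast: same next-token objective, MAE tracked
    res <- pretrain_seq_grads(model, item$x)
    return(c(res, list(metric = res$loss)))
  }
  grads <- model_backward(model, item$x, fw, dpred)
  list(loss = loss, grads = grads, model = fw$model, metric = metric)
}

#' Fine-tune on a downstream task
#'
#' End-to-end fine-tuning of all weights. Classification and regression use
#' the average-pooled last-layer representation; the task metric (accuracy /
#' MAE) is tracked per epoch on the training data.
#'
#' @param model Model whose head matches `config$task`.
#' @param labeled_data List of `list(x = sequence, y = label)` pairs
#'   (classification: integer class in `1..n_classes`; regression: numeric).
#'   For the forecast task, plain sequences are accepted.
#' @param config A [train_config()].
#' @return List with `model`, `loss_history` and `metric_history`.
#' @export
finetune <- function(model, labeled_data, config) {
  task <- config$task
  head_needed <- switch(task, forecast = "forecast",
                        classification = "classification",
                        regression = "regression")
  rt_check(model$config$head == head_needed,
           sprintf("model head '%s' does not match task '%s'", model$config$head, task),
           "config_error")
  if (task == "forecast") {
    items <- lapply(as_sequence_list(labeled_data, model$config$mode),
                    function(s) list(x = s))
  } else {
    rt_check(is.list(labeled_data) && all(vapply(labeled_data, function(it)
      is.list(it) && !is.null(it$x) && !is.null(it$y), TRUE)),
      "labeled_data must be a list of list(x=, y=) pairs", "config_error")
    if (task == "classification") {
      ys <- vapply(labeled_data, function(it) it$y, 1)
      rt_check(all(ys >= 1 & ys <= model$config$n_classes & ys == as.integer(ys)),
               "classification labels must be integers in 1..n_classes",
               "config_error")
    }
    items <- labeled_data
  }
  run_training_loop(model, items, config, config$epochs_finetune,
                    function(m, it) finetune_item_grads(m, it, task))
}

#' Check that gradients reach every parameter group
#'
#' Runs one loss/backward evaluation and reports, per top-level parameter
#' group, whether any gradient entry is non-zero. Guards against silently
#' frozen weights.
#'
#' @param model A model.
#' @param example One training item (sequence, or `list(x=, y=)` for
#'   supervised heads).
#' @param task Objective to differentiate.
#' @return Named logical vector, one entry per parameter group.
#' @export
gradient_coverage <- function(model, example,
                              task = c("forecast", "classification", "regression")) {
  task <- match.arg(task)
  g <- if (task == "forecast") pretrain_seq_grads(model, example)
       else finetune_item_grads(model, example, task)
  vapply(g$grads, function(gr) param_reduce(function(x) sum(x != 0), gr) > 0,
         TRUE)
}
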