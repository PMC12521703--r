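# Run configuration: yaml loading with strict key validation, defaults, and
# run manifests for exact re-runs.

run_config_schema <- function() {
  list(
    command = NULL,
    mode = NULL,
    seed = 1L,
    log_level = "info",
    paths = list(data = NULL, checkpoint = NULL, output = NULL, labels = NULL),
    model = list(L = 2L, d_model = 32L, n_heads = 4L, vocab_size = NULL,
                 n_channels = NULL, head = "forecast", n_classes = NULL,
                 retention_form = "parallel", chunk_size = 512L,
                 use_subsampling = TRUE, use_temporal_conv = TRUE,
                 use_decay = TRUE, use_rope = TRUE, normalize = TRUE,
                 gated_output = FALSE, d_ff = NULL, tc_kernel = 15L,
                 tc_configuration = "DW+PW", tc_norm = "batch",
                 tokenizer_kernel = 3L, tokenizer_stride = 2L,
                 rotate_by_time = TRUE, seed = 1L),
    train = list(epochs_pretrain = 20L, epochs_finetune = 5L, batch_size = 4L,
                 learning_rate = 3e-3, loss = "mse", task = "forecast",
                 warmup_frac = 0.1, clip_norm = 1.0, seed = 1L),
    generator = list(kind = NULL, n_series = 8L, length = 512L, n_channels = 1L,
                     trend_slopes = 0, periods = 64, amplitudes = 1,
                     noise_sd = 0, phase_jitter = 0,
                     n_patients = 100L, vocab_size = 50L, mean_events = 40L,
                     base_rate = 0.1, trend_codes = integer(),
                     periodic_codes = integer(), relapse_period = 90,
                     trend_strength = 3, periodic_strength = 3, seed = 1L),
    forecast = list(strategy = "trajectory", lookup = NULL, horizon = 16L,
                    step = NULL, query_times = NULL),
    evaluate = list(metric = "mae", K = c(5L, 10L, 15L))
  )
}

merge_section <- function(defaults, user, section) {
  if (is.null(user)) return(defaults)
  rt_check(is.list(user), sprintf("config section '%s' must be a mapping", section),
           "validation_error")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    rt_abort(sprintf("unknown config key%s in '%s': %s",
                     if (length(unknown) > 1L) "s" else "", section,
                     paste(unknown, collapse = ", ")),
             "validation_error")
  }
  for (nm in names(user)) defaults[[nm]] <- user[[nm]]
  defaults
}

#' Load and validate a run configuration
#'
#' Parses a yaml file, fills defaults (chunk size 512, tokenizer kernel 3 /
#' stride 2, ...), and rejects any unknown key by name.
#'
#' @param path Yaml file.
#' @return Object of class `run_config`.
#' @export
load_config <- function(path) {
  rt_check(file.exists(path), sprintf("config file not found: %s", path),
           "input_error")
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    rt_abort(sprintf("cannot parse config %s: %s", path, conditionMessage(e)),
             "parse_error"))
  raw <- raw %||% list()
  as_run_config(raw)
}

#' Build a validated run configuration from a list
#'
#' @param raw Named list of settings (as from yaml).
#' @return Object of class `run_config`.
#' @export
as_run_config <- function(raw) {
  schema <- run_config_schema()
  scalar_keys <- c("command", "mode", "seed", "log_level")
  section_keys <- setdiff(names(schema), scalar_keys)
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown)) {
    rt_abort(sprintf("unknown config key%s: %s",
                     if (length(unknown) > 1L) "s" else "",
                     paste(unknown, collapse = ", ")),
             "validation_error")
  }
  cfg <- schema
  for (k in scalar_keys) if (!is.null(raw[[k]])) cfg[[k]] <- raw[[k]]
  for (k in section_keys) cfg[[k]] <- merge_section(schema[[k]], raw[[k]], k)
  if (!is.null(cfg$mode)) {
    rt_check(cfg$mode %in% c("continuous", "discrete"),
             "mode must be 'continuous' or 'discrete'", "validation_error")
  }
  structure(cfg, class = "run_config")
}

#' Write a run configuration to yaml
#'
#' @param config A `run_config`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  yaml::write_yaml(drop_nulls(unclass(config)), path)
  invisible(path)
}

drop_nulls <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!vapply(x, is.null, TRUE)]
  lapply(x, drop_nulls)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  dump_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Write a run manifest
#'
#' Records the config hash, seed and package version so a run can be
#' reproduced exactly.
#'
#' @param config The `run_config` used.
#' @param seed Effective seed of the run.
#' @param path Output yaml file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, seed, path) {
  yaml::write_yaml(list(
    config_md5 = config_hash(config),
    seed = as.integer(seed),
    package = "retentime",
    version = as.character(utils::packageVersion("retentime")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  ), path)
  invisible(path)
}

# Model/train/generator constructors from a run_config.
config_to_model <- function(cfg) {
  m <- cfg$model
  rt_check(!is.null(cfg$mode), "config requires `mode`", "validation_error")
  model_config(L = m$L, d_model = m$d_model, n_heads = m$n_heads,
               mode = cfg$mode, n_channels = m$n_channels,
               vocab_size = m$vocab_size, head = m$head,
               n_classes = m$n_classes, retention_form = m$retention_form,
               chunk_size = m$chunk_size, use_subsampling = m$use_subsampling,
               use_temporal_conv = m$use_temporal_conv, use_decay = m$use_decay,
               use_rope = m$use_rope, normalize = m$normalize,
               gated_output = m$gated_output, d_ff = m$d_ff,
               tc_kernel = m$tc_kernel, tc_configuration = m$tc_configuration,
               tc_norm = m$tc_norm, rotate_by_time = m$rotate_by_time,
               seed = m$seed)
}

config_to_train <- function(cfg) {
  t <- cfg$train
  train_config(epochs_pretrain = t$epochs_pretrain,
               epochs_finetune = t$epochs_finetune, batch_size = t$batch_size,
               learning_rate = t$learning_rate, loss = t$loss, task = t$task,
               warmup_frac = t$warmup_frac, clip_norm = t$clip_norm,
               seed = t$seed)
}

config_to_generator <- function(cfg) {
  g <- cfg$generator
  kind <- g$kind %||% if (identical(cfg$mode, "discrete")) "events" else "biosignal"
  if (kind == "biosignal") {
    biosignal_gen_config(n_series = g$n_series, length = g$length,
                         n_channels = g$n_channels, trend_slopes = g$trend_slopes,
                         periods = g$periods, amplitudes = g$amplitudes,
                         noise_sd = g$noise_sd, phase_jitter = g$phase_jitter,
                         seed = g$seed)
  } else {
    event_gen_config(n_patients = g$n_patients, vocab_size = g$vocab_size,
                     mean_events = g$mean_events, base_rate = g$base_rate,
                     trend_codes = g$trend_codes, periodic_codes = g$periodic_codes,
                     relapse_period = g$relapse_period,
                     trend_strength = g$trend_strength,
                     periodic_strength = g$periodic_strength, seed = g$seed)
  }
}
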