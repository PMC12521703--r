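# Delimited-text readers/writers for continuous series and event logs.
# Series: header row of channel names, one row per timestep, tab-separated;
# sampling step in a yaml sidecar. Events: patient_id, timestamp, code.

series_sidecar <- function(path) paste0(path, ".meta.yaml")

#' Write a continuous series to delimited text
#'
#' One file per series (`_1`, `_2`, ... suffixes when the batch holds more
#' than one), with a yaml sidecar declaring the sampling step and channels.
#'
#' @param batch A [timeseries_batch()] or single matrix.
#' @param path Output path (suffixes inserted before the extension for
#'   multi-series batches).
#' @return Character vector of files written, invisibly.
#' @export
write_series <- function(batch, path) {
  if (is.matrix(batch)) batch <- timeseries_batch(list(batch))
  n <- length(batch$series)
  paths <- if (n == 1L) path else {
    stem <- sub("\\.([^.]+)$", "", path)
    ext <- if (grepl("\\.", basename(path))) sub(".*\\.([^.]+)$", ".\\1", path) else ""
    paste0(stem, "_", seq_len(n), ext)
  }
  for (i in seq_len(n)) {
    m <- batch$series[[i]]
    colnames(m) <- batch$channels
    utils::write.table(m, paths[i], sep = "\t", row.names = FALSE, quote = FALSE)
    yaml::write_yaml(list(step = batch$step, channels = as.list(batch$channels)),
                     series_sidecar(paths[i]))
  }
  invisible(paths)
}

#' Read a continuous series from delimited text
#'
#' @param path File written by [write_series()] (or any headered TSV of
#'   numeric channels).
#' @return A [timeseries_batch()] holding one series.
#' @export
read_series <- function(path) {
  rt_check(file.exists(path), sprintf("file not found: %s", path), "input_error")
  lines <- readLines(path)
  rt_check(length(lines) >= 2L, "series file needs a header and at least one row",
           "parse_error")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  v <- length(header)
  rows <- lapply(seq.int(2L, length(lines)), function(i) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(parts) != v || anyNA(vals)) {
      rt_abort(sprintf("malformed series row at line %d of %s", i, path),
               "parse_error")
    }
    vals
  })
  m <- do.call(rbind, rows)
  step <- 1
  if (file.exists(series_sidecar(path))) {
    meta <- yaml::read_yaml(series_sidecar(path))
    step <- meta$step %||% 1
  }
  timeseries_batch(list(m), channels = header, step = step)
}

#' Write event sequences to delimited text
#'
#' Columns `patient_id`, `timestamp`, `code`, tab-separated.
#'
#' @param sequences List of [event_sequence()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_events <- function(sequences, path) {
  if (inherits(sequences, "event_sequence")) sequences <- list(sequences)
  df <- do.call(rbind, lapply(sequences, function(s)
    data.frame(patient_id = s$patient_id, timestamp = s$times, code = s$codes)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read event sequences from delimited text
#'
#' Rows are grouped by patient in order of first appearance; timestamps must
#' be strictly increasing within each patient.
#'
#' @param path File written by [write_events()].
#' @return List of [event_sequence()] objects.
#' @export
read_events <- function(path) {
  rt_check(file.exists(path), sprintf("file not found: %s", path), "input_error")
  lines <- readLines(path)
  rt_check(length(lines) >= 2L, "event file needs a header and at least one row",
           "parse_error")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  rt_check(identical(header, c("patient_id", "timestamp", "code")),
           "event file header must be patient_id, timestamp, code", "parse_error")
  ids <- character(length(lines) - 1L)
  ts <- numeric(length(lines) - 1L)
  cd <- integer(length(lines) - 1L)
  for (i in seq.int(2L, length(lines))) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    t <- suppressWarnings(as.numeric(parts[2L]))
    k <- suppressWarnings(as.integer(parts[3L]))
    if (length(parts) != 3L || is.na(t) || is.na(k)) {
      rt_abort(sprintf("malformed event row at line %d of %s", i, path),
               "parse_error")
    }
    ids[i - 1L] <- parts[1L]; ts[i - 1L] <- t; cd[i - 1L] <- k
  }
  out <- lapply(unique(ids), function(p) {
    sel <- ids == p
    event_sequence(p, ts[sel], cd[sel])   # enforces strict time ordering
  })
  out
}
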