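#' Construct a multichannel EMG recording
#'
#' Container for a multichannel surface-EMG time series. Samples are stored as
#' a channels x time numeric matrix in arbitrary amplitude units; time is
#' implied by the sampling rate, with sample 1 at t = 0 s.
#'
#' @param samples numeric matrix, channels x time (a vector is treated as one
#'   channel).
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param channel_labels character vector, one label per channel (e.g.
#'   `c("TAp_L", "TAp_R")`).
#' @return An object of class `emg_recording` with elements `samples`,
#'   `sampling_rate`, `channel_labels`.
#' @examples
#' rec <- emg_recording(matrix(rnorm(4000), nrow = 2), 2000, c("TAp_L", "TAp_R"))
#' n_samples(rec)
#' @export
emg_recording <- function(samples, sampling_rate, channel_labels) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric matrix (channels x time)")
  }
  if (anyNA(samples)) stop("recording contains missing samples")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number (Hz)")
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(samples)) {
    stop(sprintf("%d channel labels for %d channels",
                 length(channel_labels), nrow(samples)))
  }
  if (anyDuplicated(channel_labels)) stop("duplicate channel labels")
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         channel_labels = channel_labels),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channel(s) x %d samples @ %g Hz (%.3f s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              ncol(x$samples) / x$sampling_rate))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples per channel
#' @param recording an `emg_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(recording) {
  stopifnot(inherits(recording, "emg_recording"))
  ncol(recording$samples)
}

#' Recording duration in seconds
#' @param recording an `emg_recording`.
#' @return duration in s.
#' @export
duration_s <- function(recording) {
  n_samples(recording) / recording$sampling_rate
}

#' Select channels from a recording
#' @param recording an `emg_recording`.
#' @param channels integer indices or channel labels.
#' @return an `emg_recording` with the requested channels, in request order.
#' @export
select_channels <- function(recording, channels) {
  stopifnot(inherits(recording, "emg_recording"))
  if (is.character(channels)) {
    idx <- match(channels, recording$channel_labels)
    if (anyNA(idx)) {
      stop("unknown channel label(s): ",
           paste(channels[is.na(idx)], collapse = ", "))
    }
  } else {
    idx <- as.integer(channels)
    if (any(idx < 1L | idx > nrow(recording$samples))) {
      stop("channel index out of range")
    }
  }
  emg_recording(recording$samples[idx, , drop = FALSE],
                recording$sampling_rate,
                recording$channel_labels[idx])
}

#' Read a recording from a delimited signal file plus JSON sidecar
#'
#' The signal file is a tab-delimited numeric table with a header row, one
#' column per channel, one row per sample. The sidecar is a JSON object with
#' fields `sampling_rate` (Hz) and `channel_labels` (array matching the column
#' count; column order is taken from the sidecar labels when they match the
#' header, otherwise from column order).
#'
#' @param data_path path to the signal table (`.tsv`).
#' @param meta_path path to the JSON sidecar.
#' @return an `emg_recording`.
#' @seealso [write_recording()]
#' @export
read_recording <- function(data_path, meta_path) {
  if (!file.exists(data_path)) stop("signal file not found: ", data_path)
  if (!file.exists(meta_path)) stop("metadata sidecar not found: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$sampling_rate)) stop("sidecar is missing `sampling_rate`")
  if (is.null(meta$channel_labels)) stop("sidecar is missing `channel_labels`")
  tab <- utils::read.delim(data_path, check.names = FALSE)
  if (ncol(tab) != length(meta$channel_labels)) {
    stop(sprintf("sidecar declares %d channel(s) but signal file has %d column(s)",
                 length(meta$channel_labels), ncol(tab)))
  }
  if (!all(vapply(tab, is.numeric, logical(1)))) {
    stop("signal file contains non-numeric cells")
  }
  if (all(meta$channel_labels %in% names(tab))) {
    tab <- tab[, meta$channel_labels, drop = FALSE]
  }
  emg_recording(t(as.matrix(tab)), meta$sampling_rate,
                as.character(meta$channel_labels))
}

#' Write a recording as a delimited signal file plus JSON sidecar
#'
#' @param recording an `emg_recording`.
#' @param data_path output path for the signal table.
#' @param meta_path output path for the JSON sidecar.
#' @return invisibly, `c(data_path, meta_path)`.
#' @export
write_recording <- function(recording, data_path, meta_path) {
  stopifnot(inherits(recording, "emg_recording"))
  tab <- as.data.frame(t(recording$samples))
  names(tab) <- recording$channel_labels
  utils::write.table(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                     data_path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(sampling_rate = recording$sampling_rate,
         channel_labels = recording$channel_labels,
         n_samples = ncol(recording$samples),
         amplitude_units = "arbitrary"),
    meta_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(data_path, meta_path))
}

#' Read a trial-event table
#'
#' Expects a tab-delimited table with header columns `trial_id`, `condition`,
#' `stimulus_time` (seconds from recording start) and `block`. An optional
#' `onset_override_ms` column supplies manually corrected onset latencies.
#'
#' @param path path to the events file.
#' @param recording optional `emg_recording`; when given, stimulus times are
#'   validated against its duration.
#' @return a data.frame of events sorted by `stimulus_time`.
#' @export
read_events <- function(path, recording = NULL) {
  if (!file.exists(path)) stop("events file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = c(condition = "character"))
  validate_events(tab, recording)
}

#' Validate (and sort) a trial-event table
#' @param events data.frame with columns `trial_id`, `condition`,
#'   `stimulus_time`, `block`.
#' @param recording optional `emg_recording` for range validation.
#' @return the validated data.frame sorted by `stimulus_time`.
#' @export
validate_events <- function(events, recording = NULL) {
  required <- c("trial_id", "condition", "stimulus_time", "block")
  missing <- setdiff(required, names(events))
  if (length(missing)) {
    stop("events table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(events) == 0L) return(events)
  if (anyDuplicated(events$trial_id)) stop("duplicate trial_id in events table")
  if (!is.numeric(events$stimulus_time) || anyNA(events$stimulus_time)) {
    stop("stimulus_time must be numeric and complete")
  }
  if (any(events$stimulus_time < 0)) stop("negative stimulus_time")
  if (!is.null(recording)) {
    if (any(events$stimulus_time >= duration_s(recording))) {
      stop("stimulus_time beyond recording duration")
    }
  }
  events[order(events$stimulus_time), , drop = FALSE]
}

#' Write a trial-event table
#' @param events data.frame of events (see [read_events()] for columns).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write analysis outputs as delimited tables plus a JSON run-metadata file
#'
#' Accepts any mix of the package's result objects and writes each as a
#' self-describing tab-delimited table: `coherence_estimate` ->
#' `coherence.tsv` (frequency_hz, fxx, fyy, re_fxy, im_fxy, coherence,
#' coherency, phase_rad, cl, n_segments), `cumulant_density` ->
#' `cumulant.tsv`, `doc_test` -> `doc_test.tsv`, and any data.frame under its
#' list name. Run metadata (config hash, seed, segment counts, anything passed
#' via `meta`) goes to `run_meta.json`, and a line is appended to `run_log.tsv`.
#'
#' @param results named list of result objects / data.frames.
#' @param out_dir output directory (created if needed).
#' @param meta named list of run metadata stored alongside the tables.
#' @return invisibly, character vector of file paths written.
#' @export
write_outputs <- function(results, out_dir, meta = list()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  }
  if (file.access(out_dir, mode = 2L) != 0L) {
    stop("output directory is not writable: ", out_dir)
  }
  written <- character(0)
  nm <- names(results)
  if (is.null(nm)) nm <- rep("", length(results))
  emit <- function(df, fname) {
    path <- file.path(out_dir, fname)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
  }
  for (i in seq_along(results)) {
    x <- results[[i]]
    base <- if (nzchar(nm[i])) nm[i] else sprintf("result_%02d", i)
    if (inherits(x, "coherence_estimate")) {
      emit(as.data.frame(x), paste0(base, ".tsv"))
    } else if (inherits(x, "cumulant_density")) {
      emit(as.data.frame(x), paste0(base, ".tsv"))
    } else if (inherits(x, "doc_test")) {
      emit(as.data.frame(x), paste0(base, ".tsv"))
    } else if (is.data.frame(x)) {
      emit(x, paste0(base, ".tsv"))
    } else {
      stop("write_outputs does not know how to serialize element `", base, "`")
    }
  }
  meta$written <- basename(written)
  meta$package_version <- as.character(utils::packageVersion("imcoh"))
  meta_path <- file.path(out_dir, "run_meta.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- c(written, meta_path)
  log_path <- file.path(out_dir, "run_log.tsv")
  line <- data.frame(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                     n_outputs = length(written),
                     outputs = paste(basename(written), collapse = ","))
  utils::write.table(line, log_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !file.exists(log_path),
                     append = file.exists(log_path))
  invisible(c(written, log_path))
}

#' Stable hash of a configuration list
#'
#' Deterministic content hash used to tag outputs with the configuration that
#' produced them (serialize to canonical JSON, then sum a polynomial rolling
#' hash over the bytes).
#' @param config any jsonlite-serializable object.
#' @return character scalar, 8 hex digits.
#' @export
config_hash <- function(config) {
  txt <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- as.integer(charToRaw(txt))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
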