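#' Onset-detection parameters
#'
#' Burst onset is the earliest post-stimulus time at which the rectified EMG
#' exceeds the pre-stimulus baseline mean by `k_sd` baseline standard
#' deviations continuously for at least `min_duration_ms`. Two presets cover
#' the standard tasks: the startle reflex uses 1 SD for >= 2 ms; reaction-time
#' and perturbation tasks use 2 SD for >= 5 ms. Baseline statistics are taken
#' over a window (default 100 ms) immediately preceding the stimulus.
#'
#' @param k_sd threshold in baseline-SD units.
#' @param min_duration_ms minimum supra-threshold duration (ms).
#' @param baseline_window_ms baseline window length preceding the stimulus (ms).
#' @param search_window_ms how far past the stimulus to search for an onset (ms).
#' @return an object of class `onset_params`.
#' @export
onset_params <- function(k_sd = 2, min_duration_ms = 5,
                         baseline_window_ms = 100, search_window_ms = 1000) {
  stopifnot(k_sd > 0, min_duration_ms > 0, baseline_window_ms > 0,
            search_window_ms > 0)
  structure(list(k_sd = k_sd, min_duration_ms = min_duration_ms,
                 baseline_window_ms = baseline_window_ms,
                 search_window_ms = search_window_ms),
            class = "onset_params")
}

#' Onset-parameter presets by task
#' @param task `"startle"` (1 SD, 2 ms) or one of `"startreact"`,
#'   `"perturbation"`, `"balance"`, `"ankle"` (2 SD, 5 ms).
#' @return an [onset_params()] object.
#' @export
onset_preset <- function(task = c("startle", "startreact", "perturbation",
                                  "balance", "ankle")) {
  task <- match.arg(task)
  if (task == "startle") onset_params(k_sd = 1, min_duration_ms = 2)
  else onset_params(k_sd = 2, min_duration_ms = 5)
}

#' Full-wave rectify a recording
#'
#' Elementwise absolute value; no additional filtering is applied, so the
#' low-frequency envelope carrying any common drive is preserved intact.
#'
#' @param recording an [emg_recording()].
#' @return the rectified `emg_recording`.
#' @export
rectify <- function(recording) {
  stopifnot(inherits(recording, "emg_recording"))
  recording$samples <- abs(recording$samples)
  recording
}

stimulus_sample <- function(stimulus_time, fs) {
  as.integer(round(stimulus_time * fs)) + 1L
}

#' Baseline mean and SD of a rectified channel
#'
#' Sample mean and standard deviation over the `baseline_window_ms` window
#' ending immediately before the stimulus, i.e. over
#' `[stimulus - window, stimulus)`.
#'
#' @param x numeric vector, one rectified channel.
#' @param stimulus_time stimulus time in seconds from recording start.
#' @param sampling_rate Hz.
#' @param params an [onset_params()].
#' @return list with `mean` and `sd`.
#' @export
baseline_stats <- function(x, stimulus_time, sampling_rate,
                           params = onset_params()) {
  stopifnot(is.numeric(x), inherits(params, "onset_params"))
  s_idx <- stimulus_sample(stimulus_time, sampling_rate)
  w_n <- as.integer(round(params$baseline_window_ms / 1000 * sampling_rate))
  if (s_idx - w_n < 1L) {
    stop(sprintf("need %d ms of pre-stimulus data for the baseline window",
                 params$baseline_window_ms))
  }
  win <- x[(s_idx - w_n):(s_idx - 1L)]
  list(mean = mean(win), sd = stats::sd(win))
}

#' Detect burst onset in a rectified channel
#'
#' Scans forward from the stimulus for the earliest sample at which the
#' rectified signal exceeds `baseline mean + k_sd * baseline SD` continuously
#' for at least `min_duration_ms`. Ties at sample resolution resolve to the
#' earliest sample. Returns `NA` when no qualifying crossing occurs within
#' the search window; a zero-SD baseline whose threshold is never exceeded is
#' additionally flagged via `attr(, "reason") == "degenerate_baseline"`.
#'
#' @inheritParams baseline_stats
#' @return onset latency in ms after the stimulus (numeric scalar), or
#'   `NA_real_` with a `"reason"` attribute.
#' @export
detect_onset <- function(x, stimulus_time, sampling_rate,
                         params = onset_params()) {
  bl <- baseline_stats(x, stimulus_time, sampling_rate, params)
  threshold <- bl$mean + params$k_sd * bl$sd
  s_idx <- stimulus_sample(stimulus_time, sampling_rate)
  min_n <- max(1L, as.integer(round(params$min_duration_ms / 1000 * sampling_rate)))
  search_n <- as.integer(round(params$search_window_ms / 1000 * sampling_rate))
  last <- min(length(x), s_idx + search_n + min_n - 1L)
  if (s_idx > length(x)) stop("stimulus beyond recording end")
  above <- x[s_idx:last] > threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hit <- which(runs$values & runs$lengths >= min_n & starts <= search_n)
  if (!length(hit)) {
    out <- NA_real_
    if (bl$sd == 0) attr(out, "reason") <- "degenerate_baseline"
    else attr(out, "reason") <- "no_crossing"
    return(out)
  }
  onset_offset <- starts[hit[1L]] - 1L  # samples after the stimulus sample
  onset_offset / sampling_rate * 1000
}

#' Detect onsets for every trial of a session
#'
#' Applies [detect_onset()] per event on the given channel of a rectified
#' recording. When the events table carries an `onset_override_ms` column,
#' non-missing overrides replace the automatic detection (standing in for
#' visual inspection and manual correction of onsets).
#'
#' @param recording a rectified [emg_recording()].
#' @param events validated events data.frame.
#' @param channel channel label or index to detect on.
#' @param params an [onset_params()].
#' @return `events` with added columns `onset_latency_ms` (NA when absent)
#'   and `onset_source` (`"auto"`, `"override"`, or `"none"`).
#' @export
detect_onsets <- function(recording, events, channel = 1L,
                          params = onset_params()) {
  stopifnot(inherits(recording, "emg_recording"))
  events <- validate_events(events, recording)
  x <- select_channels(recording, channel)$samples[1L, ]
  lat <- rep(NA_real_, nrow(events))
  src <- rep("none", nrow(events))
  for (i in seq_len(nrow(events))) {
    ov <- if ("onset_override_ms" %in% names(events))
      events$onset_override_ms[i] else NA_real_
    if (!is.na(ov)) {
      lat[i] <- ov
      src[i] <- "override"
    } else {
      l <- detect_onset(x, events$stimulus_time[i], recording$sampling_rate,
                        params)
      if (!is.na(l)) {
        lat[i] <- l
        src[i] <- "auto"
      }
    }
  }
  events$onset_latency_ms <- lat
  events$onset_source <- src
  events
}

#' Response incidence, overall and per block
#'
#' Incidence is the percentage of trials with a detected onset relative to
#' the total trial count.
#'
#' @param events events data.frame (must include `block`).
#' @param onsets numeric vector of onset latencies aligned with `events` rows
#'   (`NA` = no response); defaults to `events$onset_latency_ms`.
#' @return list with `overall_pct` and `per_block` (data.frame: `block`,
#'   `n_trials`, `n_detected`, `incidence_pct`).
#' @export
incidence <- function(events, onsets = events$onset_latency_ms) {
  if (nrow(events) == 0L) stop("incidence undefined for zero trials")
  if (length(onsets) != nrow(events)) {
    stop("`onsets` must align with the event rows")
  }
  detected <- !is.na(onsets)
  per_block <- do.call(rbind, lapply(split(detected, events$block), function(d) {
    data.frame(n_trials = length(d), n_detected = sum(d),
               incidence_pct = 100 * mean(d))
  }))
  per_block <- cbind(block = as.integer(rownames(per_block)), per_block)
  rownames(per_block) <- NULL
  list(overall_pct = 100 * mean(detected), per_block = per_block)
}

#' Segment geometry for spectral analysis
#'
#' `analysis_samples` raw samples are taken per trial and zero-padded to
#' `padded_samples` before the transform; the padding refines the plotted
#' frequency grid (spacing `sampling_rate / padded_samples`) while the
#' underlying resolution remains `sampling_rate / analysis_samples`.
#' `offset_ms` shifts the window start relative to the detected onset and is
#' restricted to the moving-window grid 0, 10, ..., 80 ms.
#'
#' @param analysis_samples samples entering the transform (256 for the
#'   startle preset, 512 otherwise).
#' @param padded_samples segment length after zero padding (>=
#'   `analysis_samples`).
#' @param offset_ms window-start shift after the onset, in
#'   `{0, 10, ..., 80}` ms.
#' @return an object of class `segment_spec`.
#' @export
segment_spec <- function(analysis_samples = 512, padded_samples = 1024,
                         offset_ms = 0) {
  stopifnot(analysis_samples >= 2, padded_samples >= analysis_samples)
  if (!offset_ms %in% seq(0, 80, by = 10)) {
    stop("offset_ms must be one of 0, 10, ..., 80")
  }
  structure(list(analysis_samples = as.integer(analysis_samples),
                 padded_samples = as.integer(padded_samples),
                 offset_ms = offset_ms),
            class = "segment_spec")
}

#' Segment-geometry presets by task
#' @param task `"startle"` (256 samples padded to 512) or any other task
#'   (512 padded to 1024).
#' @return a [segment_spec()].
#' @export
segment_preset <- function(task = c("startle", "startreact", "perturbation",
                                    "balance", "ankle")) {
  task <- match.arg(task)
  if (task == "startle") segment_spec(256, 512) else segment_spec(512, 1024)
}

#' Moving-RMS envelope
#'
#' Root-mean-square over a centered moving window; at the edges the window is
#' truncated to the available samples. Used for the sustained-activity screen,
#' because raw rectified EMG touches zero between motor-unit potentials and a
#' samplewise threshold test would reject everything.
#'
#' @param x numeric vector (rectified signal).
#' @param sampling_rate Hz.
#' @param window_ms RMS window length (ms), default 10.
#' @return numeric vector, same length as `x`.
#' @export
moving_rms <- function(x, sampling_rate, window_ms = 10) {
  k <- max(1L, as.integer(round(window_ms / 1000 * sampling_rate)))
  half_lo <- (k - 1L) %/% 2L
  half_hi <- k - 1L - half_lo
  n <- length(x)
  cs <- cumsum(c(0, x^2))
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

new_trial_segment <- function(x, sampling_rate, spec, trial_id = NA,
                              condition = NA_character_,
                              channel_pair = c("ch1", "ch2"),
                              onset_latency_ms = NA_real_) {
  structure(list(x = x, sampling_rate = sampling_rate,
                 analysis_samples = ncol(x),
                 offset_ms = spec$offset_ms,
                 trial_id = trial_id, condition = condition,
                 channel_pair = channel_pair,
                 onset_latency_ms = onset_latency_ms,
                 accepted = TRUE),
            class = "trial_segment")
}

rejected_segment <- function(reason, trial_id = NA, offset_ms = NA) {
  structure(list(accepted = FALSE, reason = reason, trial_id = trial_id,
                 offset_ms = offset_ms),
            class = "trial_segment")
}

#' Extract and screen one analysis segment
#'
#' Takes the window of `spec$analysis_samples` rectified samples starting at
#' `onset_sample + offset` from both channels, and accepts it only if on both
#' channels the smoothed rectified envelope (moving RMS, `rms_window_ms`)
#' exceeds `baseline mean + screen_k_sd * baseline SD` at every sample of the
#' window — the sustained-activity criterion. Rejected segments carry a
#' `reason` (`"below_threshold_ch1"` / `"..._ch2"`).
#'
#' @param pair a rectified two-channel [emg_recording()].
#' @param onset_sample 1-based sample index of the detected onset.
#' @param spec a [segment_spec()].
#' @param baseline list of two `list(mean, sd)` baseline statistics, one per
#'   channel (from [baseline_stats()]).
#' @param screen_k_sd SD multiplier of the sustained-activity threshold
#'   (default 2).
#' @param rms_window_ms smoothing window for the envelope (ms).
#' @param trial_id,condition carried through to the segment.
#' @param envelope optional 2 x n matrix of precomputed [moving_rms()]
#'   envelopes (one row per channel) to avoid recomputation across trials.
#' @return a `trial_segment` (check `$accepted`).
#' @export
extract_segment <- function(pair, onset_sample, spec, baseline,
                            screen_k_sd = 2, rms_window_ms = 10,
                            trial_id = NA, condition = NA_character_,
                            envelope = NULL) {
  stopifnot(inherits(pair, "emg_recording"), nrow(pair$samples) == 2L,
            inherits(spec, "segment_spec"))
  fs <- pair$sampling_rate
  start <- as.integer(onset_sample) +
    as.integer(round(spec$offset_ms / 1000 * fs))
  idx <- start:(start + spec$analysis_samples - 1L)
  if (start < 1L || idx[length(idx)] > ncol(pair$samples)) {
    stop("analysis window out of recording bounds")
  }
  for (ch in 1:2) {
    env <- if (is.null(envelope)) moving_rms(pair$samples[ch, ], fs, rms_window_ms)
           else envelope[ch, ]
    thr <- baseline[[ch]]$mean + screen_k_sd * baseline[[ch]]$sd
    if (any(env[idx] <= thr)) {
      return(rejected_segment(paste0("below_threshold_ch", ch),
                              trial_id, spec$offset_ms))
    }
  }
  new_trial_segment(pair$samples[, idx, drop = FALSE], fs, spec,
                    trial_id = trial_id, condition = condition,
                    channel_pair = pair$channel_labels)
}

#' Extract the nine moving-window candidates for one trial
#'
#' One candidate per offset in 0, 10, ..., 80 ms after the onset, each
#' independently screened by the sustained-activity criterion. Windows that
#' fall outside the recording are returned as rejected segments with reason
#' `"out_of_bounds"`.
#'
#' @inheritParams extract_segment
#' @param offsets window-start offsets in ms (default `seq(0, 80, 10)`).
#' @return list of `trial_segment`s, one per offset, names `"0"` ... `"80"`.
#' @export
moving_windows <- function(pair, onset_sample, spec, baseline,
                           screen_k_sd = 2, rms_window_ms = 10,
                           offsets = seq(0, 80, by = 10),
                           trial_id = NA, condition = NA_character_,
                           envelope = NULL) {
  out <- lapply(offsets, function(off) {
    sp <- segment_spec(spec$analysis_samples, spec$padded_samples, off)
    tryCatch(
      extract_segment(pair, onset_sample, sp, baseline, screen_k_sd,
                      rms_window_ms, trial_id, condition, envelope),
      error = function(e) rejected_segment("out_of_bounds", trial_id, off))
  })
  names(out) <- as.character(offsets)
  out
}
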