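#' Analysis configuration for a task preset
#'
#' Bundles the per-task parameters of the full pipeline: onset-detection
#' rules, segment geometry, band definitions and significance level. The
#' presets resolve to the standard parameter pairs — startle: onset threshold
#' 1 SD for 2 ms, 256-sample windows padded to 512; StartReact /
#' perturbation / balance / ankle: 2 SD for 5 ms, 512-sample windows padded
#' to 1024 — with the matching band edges from [band_preset()].
#'
#' @param task one of `"startle"`, `"startreact"`, `"perturbation"`,
#'   `"balance"`, `"ankle"`.
#' @param channel_pair length-2 vector of channel labels or indices forming
#'   the analysis pair (e.g. homologous left/right muscles for intermuscular
#'   coherence, proximal/distal sites for intramuscular coherence).
#' @param onset_channel channel used for onset detection (default: first of
#'   the pair).
#' @param onset optional [onset_params()] overriding the preset.
#' @param segment optional [segment_spec()] overriding the preset.
#' @param bands optional named list of `c(lower, upper)` band edges.
#' @param alpha significance level for CL and tests.
#' @param screen_k_sd SD multiplier of the sustained-activity screen.
#' @param rms_window_ms envelope smoothing window for the screen (ms).
#' @param seed integer seed recorded with the run.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(task = c("startle", "startreact", "perturbation",
                                     "balance", "ankle"),
                            channel_pair = c(1L, 2L),
                            onset_channel = channel_pair[1L],
                            onset = NULL, segment = NULL, bands = NULL,
                            alpha = 0.05, screen_k_sd = 2,
                            rms_window_ms = 10, seed = 1L) {
  task <- match.arg(task)
  stopifnot(length(channel_pair) == 2L, alpha > 0, alpha < 1)
  if (is.null(onset)) onset <- onset_preset(task)
  if (is.null(segment)) segment <- segment_preset(task)
  if (is.null(bands)) bands <- band_preset(task)
  stopifnot(inherits(onset, "onset_params"), inherits(segment, "segment_spec"))
  structure(list(task = task, channel_pair = channel_pair,
                 onset_channel = onset_channel, onset = onset,
                 segment = segment, bands = bands, alpha = alpha,
                 screen_k_sd = screen_k_sd, rms_window_ms = rms_window_ms,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Run the full single-condition pipeline on one session
#'
#' Executes the chain rectify -> onset detection -> sustained-activity
#' screening -> zero-padded transform -> periodogram averaging on one
#' recording, then derives the coherence estimate, the cumulant density and
#' the crosstalk diagnostic. One disjoint segment is taken per trial, at the
#' window offset in `config$segment`.
#'
#' @param recording an [emg_recording()] (raw; rectification happens here).
#' @param events events data.frame; when `condition` is given only matching
#'   trials are used.
#' @param config an [analysis_config()].
#' @param condition optional condition label to filter `events`.
#' @return an object of class `condition_result`: `spectra`
#'   (`spectral_matrix`), `coherence`, `cumulant`, `crosstalk`, `events`
#'   (with onset columns), `segments` (accepted `trial_segment`s), `report`
#'   (found / accepted / rejection reasons and `L`), `config`.
#' @export
run_condition <- function(recording, events, config, condition = NULL) {
  stopifnot(inherits(recording, "emg_recording"),
            inherits(config, "analysis_config"))
  events <- validate_events(events, recording)
  if (!is.null(condition)) {
    events <- events[events$condition == condition, , drop = FALSE]
  }
  if (nrow(events) == 0L) stop("no events to analyze")
  pair <- select_channels(recording, config$channel_pair)
  rect <- rectify(pair)
  onset_ch <- if (is.character(config$onset_channel)) {
    match(config$onset_channel, pair$channel_labels)
  } else {
    match(config$onset_channel, config$channel_pair)
  }
  if (is.na(onset_ch)) onset_ch <- 1L
  events <- detect_onsets(rect, events, channel = onset_ch, config$onset)
  fs <- rect$sampling_rate
  envelope <- rbind(
    moving_rms(rect$samples[1L, ], fs, config$rms_window_ms),
    moving_rms(rect$samples[2L, ], fs, config$rms_window_ms))

  segments <- list()
  reasons <- character(0)
  for (i in seq_len(nrow(events))) {
    if (is.na(events$onset_latency_ms[i])) {
      reasons <- c(reasons, "no_onset")
      next
    }
    onset_sample <- stimulus_sample(events$stimulus_time[i], fs) +
      as.integer(round(events$onset_latency_ms[i] / 1000 * fs))
    baseline <- lapply(1:2, function(ch) {
      baseline_stats(rect$samples[ch, ], events$stimulus_time[i], fs,
                     config$onset)
    })
    seg <- tryCatch(
      extract_segment(rect, onset_sample, config$segment, baseline,
                      config$screen_k_sd, config$rms_window_ms,
                      trial_id = events$trial_id[i],
                      condition = events$condition[i],
                      envelope = envelope),
      error = function(e) rejected_segment("out_of_bounds",
                                           events$trial_id[i],
                                           config$segment$offset_ms))
    if (seg$accepted) segments <- c(segments, list(seg))
    else reasons <- c(reasons, seg$reason)
  }
  if (!length(segments)) {
    stop("no segments accepted; rejection reasons: ",
         paste(sprintf("%s (%d)", names(table(reasons)), table(reasons)),
               collapse = ", "))
  }
  S <- estimate_spectra(segments, config$segment$padded_samples)
  C <- coherence(S, config$alpha)
  Q <- cumulant_density(S)
  xt <- crosstalk_flag(C, Q)
  report <- list(
    n_trials = nrow(events),
    n_onsets = sum(!is.na(events$onset_latency_ms)),
    segments_found = sum(!is.na(events$onset_latency_ms)),
    segments_accepted = length(segments),
    segments_rejected = length(reasons),
    rejection_reasons = if (length(reasons)) table(reasons) else NULL,
    L = S$L,
    config_hash = config_hash(unclass(config)[
      c("task", "alpha", "screen_k_sd", "rms_window_ms")])
  )
  structure(list(spectra = S, coherence = C, cumulant = Q, crosstalk = xt,
                 events = events, segments = segments, report = report,
                 config = config),
            class = "condition_result")
}

#' @export
print.condition_result <- function(x, ...) {
  cat(sprintf("<condition_result> task %s: %d/%d trials -> L = %d segments\n",
              x$config$task, x$report$segments_accepted, x$report$n_trials,
              x$report$L))
  print(x$coherence)
  invisible(x)
}

pool_condition_results <- function(results, alpha) {
  stopifnot(length(results) >= 1L)
  lapply(results, function(r) stopifnot(inherits(r, "condition_result")))
  S <- pool_records(lapply(results, `[[`, "spectra"))
  coherence(S, alpha)
}

#' Compare two conditions: per-bin doc test plus band-mean table
#'
#' Pools each side across participants (segment-weighted spectra), runs the
#' chi-squared difference-of-coherence test between the pooled estimates at
#' every frequency bin, and tabulates per-participant Fisher-transformed
#' band means for both conditions and every configured band.
#'
#' @param results_a,results_b a `condition_result` or list of per-participant
#'   `condition_result`s for each condition.
#' @param config an [analysis_config()] (supplies bands and alpha).
#' @param labels length-2 condition labels for the output tables.
#' @return list of class `comparison_result`: `doc` (`doc_test`),
#'   `pooled` (list of two pooled `coherence_estimate`s), `band_means`
#'   (data.frame: participant, task, band, value), `labels`.
#' @export
run_comparison <- function(results_a, results_b, config,
                           labels = c("A", "B")) {
  as_list <- function(x) if (inherits(x, "condition_result")) list(x) else x
  results_a <- as_list(results_a)
  results_b <- as_list(results_b)
  pooled_a <- pool_condition_results(results_a, config$alpha)
  pooled_b <- pool_condition_results(results_b, config$alpha)
  doc <- doc_test(list(pooled_a, pooled_b), config$alpha)

  bands <- lapply(names(config$bands), function(nm) {
    resolve_band(config$bands[[nm]][1], config$bands[[nm]][2],
                 pooled_a$freq, nm)
  })
  names(bands) <- names(config$bands)
  rows <- list()
  for (side in 1:2) {
    res <- list(results_a, results_b)[[side]]
    for (p in seq_along(res)) {
      for (nm in names(bands)) {
        rows[[length(rows) + 1L]] <- data.frame(
          participant = p, task = labels[side], band = nm,
          value = band_mean(res[[p]]$coherence, bands[[nm]]))
      }
    }
  }
  structure(list(doc = doc, pooled = list(pooled_a, pooled_b),
                 band_means = do.call(rbind, rows), labels = labels),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s vs %s\n", x$labels[1], x$labels[2]))
  print(x$doc)
  invisible(x)
}

#' Moving-window comparison across post-onset offsets
#'
#' Repeats the two-condition comparison with the analysis window shifted in
#' 10 ms increments from the muscle onset (0 ms) up to 80 ms after onset:
#' for each offset, both conditions are re-segmented, re-screened, pooled
#' across sessions and compared with the difference-of-coherence test.
#'
#' @param sessions a single `list(recording, events)` or a list of such
#'   per-participant sessions.
#' @param config an [analysis_config()] (typically the StartReact preset).
#' @param conditions length-2 vector of condition labels compared at every
#'   offset (default `c("LAS", "MAS")`).
#' @param offsets window offsets in ms (default `seq(0, 80, 10)`).
#' @return object of class `moving_window_result`: `per_offset` (named list
#'   of `comparison_result`s) and `table` (long data.frame: offset_ms,
#'   frequency_hz, coherence in each condition, chi2, threshold,
#'   significant).
#' @export
run_moving_window <- function(sessions, config,
                              conditions = c("LAS", "MAS"),
                              offsets = seq(0, 80, by = 10)) {
  if (!is.null(sessions$recording)) sessions <- list(sessions)
  stopifnot(length(conditions) == 2L)
  per_offset <- list()
  rows <- list()
  for (off in offsets) {
    cfg <- config
    cfg$segment <- segment_spec(config$segment$analysis_samples,
                                config$segment$padded_samples, off)
    res_a <- lapply(sessions, function(s)
      run_condition(s$recording, s$events, cfg, conditions[1L]))
    res_b <- lapply(sessions, function(s)
      run_condition(s$recording, s$events, cfg, conditions[2L]))
    cmp <- run_comparison(res_a, res_b, cfg, conditions)
    per_offset[[as.character(off)]] <- cmp
    rows[[length(rows) + 1L]] <- data.frame(
      offset_ms = off,
      frequency_hz = cmp$doc$freq,
      coherence_a = cmp$pooled[[1L]]$coherence,
      coherence_b = cmp$pooled[[2L]]$coherence,
      cl_a = cmp$pooled[[1L]]$cl, cl_b = cmp$pooled[[2L]]$cl,
      chi2 = cmp$doc$chi2, threshold = cmp$doc$threshold,
      significant = cmp$doc$significant)
  }
  structure(list(per_offset = per_offset, table = do.call(rbind, rows),
                 conditions = conditions),
            class = "moving_window_result")
}

#' @export
print.moving_window_result <- function(x, ...) {
  cat(sprintf("<moving_window_result> %s vs %s at offsets %s ms\n",
              x$conditions[1], x$conditions[2],
              paste(names(x$per_offset), collapse = ", ")))
  invisible(x)
}
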