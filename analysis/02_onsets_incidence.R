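#!/usr/bin/env Rscript
# Burst onset latencies and response incidence on the simulated cohort:
# detect onsets per trial against the pre-stimulus baseline and compare the
# estimates with the generator's ground truth.

library(imcoh)

cohort <- readRDS("results/01_cohort/cohort.rds")
out_dir <- "results/02_onsets"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# 2 SD / 5 ms rule over a 200 ms response window: on continuously active
# synthetic baselines the short 1 SD / 2 ms startle rule needs the manual
# correction it was historically paired with (see the methods vignette)
params <- onset_params(k_sd = 2, min_duration_ms = 5, search_window_ms = 200)

rows <- list()
for (cond in names(cohort)) {
  for (p in seq_along(cohort[[cond]])) {
    ses <- cohort[[cond]][[p]]
    det <- detect_onsets(rectify(ses$recording), ses$events, 1, params)
    truth <- ses$truth$trials
    inc <- incidence(det)
    err <- det$onset_latency_ms - truth$onset_latency_ms
    rows[[length(rows) + 1L]] <- data.frame(
      condition = cond, participant = p,
      median_latency_ms = median(det$onset_latency_ms, na.rm = TRUE),
      true_median_latency_ms = median(truth$onset_latency_ms, na.rm = TRUE),
      median_abs_error_ms = median(abs(err), na.rm = TRUE),
      incidence_pct = inc$overall_pct,
      true_incidence_pct = 100 * mean(truth$has_burst))
  }
}
tab <- do.call(rbind, rows)
write_outputs(list(onset_summary = tab), out_dir,
              meta = list(step = "02_onsets_incidence",
                          k_sd = params$k_sd,
                          min_duration_ms = params$min_duration_ms,
                          search_window_ms = params$search_window_ms))

cat("Per-participant onset summary:\n")
print(tab, row.names = FALSE, digits = 3)
cat(sprintf("\nGrand median detected latency: %.1f ms (generator median 59.1 ms)\n",
            median(tab$median_latency_ms)))
cat(sprintf("Grand median |latency error|: %.2f ms\n",
            median(tab$median_abs_error_ms)))
cat("Note: on amplitude-modulated bursts with a 15 ms rise, the 2 SD / 5 ms\n",
    "rule fires part-way up the rise once a sustained run clears the\n",
    "threshold, so detected latencies sit systematically above the true\n",
    "envelope onset; incidence is unaffected. See the methods vignette.\n",
    sep = "")
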