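#!/usr/bin/env Rscript
# Crosstalk diagnostics: the zero-lag cumulant peak + broadband coherence
# signature should fire on linearly mixed channels, and stay silent for
# independent channels and for a genuine narrowband common drive.

library(imcoh)

out_dir <- "results/05_crosstalk"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

diag_for <- function(seed, crosstalk = 0, drive = list(), L = 50) {
  cfg <- synthetic_emg_config(duration = L * 256 / 2000 + 0.1,
                              common_drive = drive,
                              crosstalk_coeff = crosstalk, seed = seed)
  rec <- rectify(generate_emg_pair(cfg)$recording)
  segs <- lapply(seq(1L, by = 256L, length.out = L), function(s)
    segment_periodogram(rec$samples[, s:(s + 255L)], 512, 2000))
  S <- estimate_spectra(segs)
  fl <- crosstalk_flag(coherence(S), cumulant_density(S))
  data.frame(flag = fl$flag, central_peak = fl$central_peak,
             broadband = fl$broadband, peak_lag_ms = fl$peak_lag_ms,
             frac_above_cl = fl$frac_above_cl)
}

rows <- list()
for (r in 1:10) {
  rows[[length(rows) + 1]] <- cbind(case = "mixed_0.5", rep = r,
                                    diag_for(6000 + r, crosstalk = 0.5))
  rows[[length(rows) + 1]] <- cbind(case = "independent", rep = r,
                                    diag_for(6100 + r))
  rows[[length(rows) + 1]] <- cbind(case = "narrowband_12hz", rep = r,
                                    diag_for(6200 + r,
                                             drive = list(c(12, 0.5))))
}
tab <- do.call(rbind, rows)
write_outputs(list(crosstalk_diagnostics = tab), out_dir,
              meta = list(step = "05_crosstalk_check", L = 50,
                          mixing_coeff = 0.5))

cat("Crosstalk flag rate by case (10 replicates each):\n")
print(aggregate(flag ~ case, tab, mean), row.names = FALSE)
cat("\nMedian |q|-peak lag and breadth by case:\n")
print(aggregate(cbind(peak_lag_ms, frac_above_cl) ~ case, tab, median),
      row.names = FALSE)
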