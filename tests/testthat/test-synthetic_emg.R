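test_that("generation is bit-identical under a fixed seed", {
  ev <- trial_events(3, "LAS")
  cfg <- synthetic_emg_config(duration = 8, common_drive = list(c(12, 0.4)),
                              burst = burst_spec(), seed = 77)
  a <- generate_emg_pair(cfg, ev)
  b <- generate_emg_pair(cfg, ev)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth$trials, b$truth$trials)
})

test_that("configs that would produce negative envelopes are rejected", {
  expect_error(synthetic_emg_config(common_drive = list(c(10, 0.6),
                                                        c(20, 0.5))),
               "negative envelope")
  expect_error(
    synthetic_emg_config(common_drive = list(c(10, 0.5)),
                         private_drive = list(list(c(25, 0.6)), list())),
    "negative envelope")
  # depth and band sanity
  expect_error(synthetic_emg_config(common_drive = list(c(10, 1.5))),
               "depth")
  expect_error(synthetic_emg_config(carrier_band = c(20, 1500)))
})

test_that("crosstalk injection mixes channels as declared", {
  rec <- stationary_pair(4, seed = 3)
  expect_identical(inject_crosstalk(rec, 0), rec)
  mixed <- inject_crosstalk(rec, 0.3)
  expect_equal(mixed$samples[1, ],
               0.7 * rec$samples[1, ] + 0.3 * rec$samples[2, ])
  one_ch <- emg_recording(matrix(rnorm(100), 1), 2000, "a")
  expect_error(inject_crosstalk(one_ch, 0.3), "2 channels")
})

test_that("burst onset latencies match the configured median and incidence", {
  n_tr <- 220
  ev <- trial_events(n_tr, "LAS", start_s = 0.5, spacing_s = 0.6)
  cfg <- synthetic_emg_config(
    duration = 0.5 + n_tr * 0.6 + 0.5,
    burst = burst_spec(onset_median_ms = 59.1, onset_iqr_ms = 4.7,
                       incidence = 1),
    seed = 21)
  truth <- generate_emg_pair(cfg, ev)$truth$trials
  expect_true(all(truth$has_burst))
  expect_lt(abs(median(truth$onset_latency_ms) - 59.1), 2)
  expect_true(all(truth$onset_sample >= 1 &
                    truth$onset_sample <= 0.5 + n_tr * 0.6 * 2000 + 1000))

  cfg2 <- synthetic_emg_config(
    duration = 0.5 + n_tr * 0.6 + 0.5,
    burst = burst_spec(incidence = 0.5), seed = 22)
  truth2 <- generate_emg_pair(cfg2, ev)$truth$trials
  p_hat <- mean(truth2$has_burst)
  ci <- stats::binom.test(sum(truth2$has_burst), n_tr, 0.5)$conf.int
  expect_true(0.5 >= ci[1] && 0.5 <= ci[2])
  expect_gt(p_hat, 0.35)
  expect_lt(p_hat, 0.65)
})

test_that("a shared 12 Hz envelope modulation is recovered at the nearest bin", {
  rec <- stationary_pair(100, seed = 31, common_drive = list(c(12, 0.5)))
  segs <- cut_segments(rec, 256, 100)
  C <- coherence(estimate_spectra(segs, 512))
  use <- which(C$freq > 0)
  peak_bin <- use[which.max(C$coherence[use])]
  expect_equal(peak_bin, which.min(abs(C$freq - 12)))
})

test_that("independent pairs show ~5% of bins above the confidence limit", {
  above <- logical(0)
  for (seed in 1:5) {
    # 100-sample gaps keep the disjoint segments effectively independent,
    # matching the estimator's one-segment-per-trial assumption
    rec <- stationary_pair(200, seed = 100 + seed, gap = 100L)
    segs <- cut_segments(rec, 256, 200, gap = 100L)
    C <- coherence(estimate_spectra(segs, 256))
    use <- C$freq > 0 & C$freq < 1000 & !C$zero_power
    above <- c(above, C$coherence[use] > C$cl)
  }
  rate <- mean(above)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("generator configs round-trip through YAML and JSON files", {
  dir <- withr::local_tempdir()
  yml <- file.path(dir, "cfg.yaml")
  writeLines(c(
    "duration: 8",
    "common_drive:",
    "  - [12, 0.5]",
    "burst:",
    "  LAS: {onset_median_ms: 105.0, onset_iqr_ms: 12.9}",
    "  MAS: {onset_median_ms: 174.8, onset_iqr_ms: 37.1}",
    "drive_gate_ms: [0, 80]",
    "drive_conditions: [LAS]",
    "seed: 9"), yml)
  cfg <- read_synthetic_config(yml)
  expect_s3_class(cfg, "synthetic_emg_config")
  expect_equal(cfg$common_drive[[1]], c(12, 0.5))
  expect_equal(cfg$burst$MAS$onset_median_ms, 174.8)
  expect_equal(cfg$drive_gate_ms, c(0, 80))
  expect_equal(cfg$seed, 9L)

  jsn <- file.path(dir, "cfg.json")
  jsonlite::write_json(list(duration = 5, seed = 3,
                            common_drive = list(c(20, 0.3))),
                       jsn, auto_unbox = TRUE, digits = NA)
  cfg2 <- read_synthetic_config(jsn)
  expect_equal(cfg2$common_drive[[1]], c(20, 0.3))
  expect_null(cfg2$burst)
  # a config file is a complete recipe: same file, same signals
  ev <- trial_events(2, "LAS", spacing_s = 1.5)
  expect_identical(generate_emg_pair(read_synthetic_config(yml), ev)$recording,
                   generate_emg_pair(cfg, ev)$recording)
})

test_that("zero-lag mixing puts the cumulant-density peak at lag zero", {
  rec <- stationary_pair(60, seed = 41, crosstalk = 0.5)
  S <- estimate_spectra(cut_segments(rec, 256, 60), 512)
  Q <- cumulant_density(S)
  expect_equal(Q$lag_ms[which.max(abs(Q$q))], 0)
})
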