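# Shared fixtures and independent oracles, all built in code at test time.

# Explicit O(n^2) discrete Fourier transform; deliberately independent of
# stats::fft so it can serve as an oracle for the spectral path.
oracle_dft <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  vapply(k, function(kk) {
    sum(x * exp(-2i * pi * kk * (0:(n - 1)) / n))
  }, complex(1))
}

# Brute-force two-loop (segments x bins) spectral estimate from a list of
# 2 x N matrices, using oracle_dft and explicit accumulation.
oracle_spectra <- function(mats, padded, fs) {
  L <- length(mats)
  N <- ncol(mats[[1]])
  P <- padded
  fxx <- fyy <- numeric(P)
  fxy <- complex(P)
  for (m in mats) {
    x <- c(m[1, ] - mean(m[1, ]), rep(0, P - N))
    y <- c(m[2, ] - mean(m[2, ]), rep(0, P - N))
    X <- oracle_dft(x)
    Y <- oracle_dft(y)
    for (k in seq_len(P)) {
      fxx[k] <- fxx[k] + Re(X[k] * Conj(X[k])) / (2 * pi * N)
      fyy[k] <- fyy[k] + Re(Y[k] * Conj(Y[k])) / (2 * pi * N)
      fxy[k] <- fxy[k] + Conj(X[k]) * Y[k] / (2 * pi * N)
    }
  }
  list(fxx = fxx / L, fyy = fyy / L, fxy = fxy / L)
}

# White-noise pair periodograms (independent channels), no zero padding so
# frequency bins stay independent.
white_periodograms <- function(L, N = 256, fs = 2000) {
  lapply(seq_len(L), function(i) {
    segment_periodogram(rbind(stats::rnorm(N), stats::rnorm(N)), N, fs)
  })
}

# Coherence estimate for a bivariate process with a genuinely shared
# component: x = s + a*n1, y = s + a*n2 gives flat true coherence
# 1 / (1 + a^2)^2 at every bin.
shared_signal_estimate <- function(L, a = 1, N = 256, fs = 2000) {
  coherence(estimate_spectra(lapply(seq_len(L), function(i) {
    s <- stats::rnorm(N)
    segment_periodogram(rbind(s + a * stats::rnorm(N),
                              s + a * stats::rnorm(N)), N, fs)
  })))
}

# Cut a stationary two-channel recording into disjoint analysis segments,
# optionally separated by a gap so segments are effectively independent.
cut_segments <- function(recording, analysis_samples, L = NULL, gap = 0L) {
  n <- n_samples(recording)
  starts <- seq(1L, n - analysis_samples + 1L, by = analysis_samples + gap)
  if (!is.null(L)) starts <- starts[seq_len(L)]
  spec <- segment_spec(analysis_samples, 2L * analysis_samples)
  lapply(starts, function(s) {
    imcoh:::new_trial_segment(
      recording$samples[, s:(s + analysis_samples - 1L), drop = FALSE],
      recording$sampling_rate, spec)
  })
}

# Stationary rectified synthetic pair long enough for L disjoint segments
# separated by `gap` samples.
stationary_pair <- function(L, analysis_samples = 256, seed = 1,
                            common_drive = list(), crosstalk = 0, gap = 0L) {
  dur <- (L * (analysis_samples + gap)) / 2000 + 0.1
  cfg <- synthetic_emg_config(duration = dur, common_drive = common_drive,
                              crosstalk_coeff = crosstalk, seed = seed)
  rectify(generate_emg_pair(cfg)$recording)
}

# One synthetic interleaved LAS/MAS session for the moving-window analyses:
# the 12 Hz common drive is confined to the first 80 ms after the onset of
# LAS bursts only.
make_mw_session <- function(seed, n_per_cond = 45, depth = 0.5,
                            gate = c(0, 80)) {
  n_tr <- 2L * n_per_cond
  set.seed(seed + 5e5)
  conds <- rep(c("LAS", "MAS"), n_per_cond)
  ev <- data.frame(trial_id = seq_len(n_tr),
                   condition = conds[sample(n_tr)],
                   stimulus_time = 1 + (seq_len(n_tr) - 1) * 1.5,
                   block = 1L)
  cfg <- synthetic_emg_config(
    duration = 1 + n_tr * 1.5 + 1,
    common_drive = list(c(12, depth)),
    burst = list(LAS = burst_spec(105.0, 12.9, rise_ms = 20,
                                  plateau_ms = 400, fall_ms = 50),
                 MAS = burst_spec(174.8, 37.1, rise_ms = 20,
                                  plateau_ms = 400, fall_ms = 50)),
    drive_gate_ms = gate, drive_conditions = "LAS", seed = seed)
  sim <- generate_emg_pair(cfg, ev)
  list(recording = sim$recording, events = ev)
}

# A short startle-like session with burst + common drive, for pipeline tests.
make_startle_session <- function(seed, n_trials = 20, incidence = 1,
                                 depth = 0.5) {
  ev <- trial_events(n_trials, "LAS", start_s = 1, spacing_s = 1.2)
  cfg <- synthetic_emg_config(
    duration = 1 + n_trials * 1.2 + 0.5,
    common_drive = if (depth > 0) list(c(12, depth)) else list(),
    burst = burst_spec(59.1, 4.7, rise_ms = 15, plateau_ms = 220,
                       fall_ms = 40, incidence = incidence),
    seed = seed)
  sim <- generate_emg_pair(cfg, ev)
  list(recording = sim$recording, events = ev, truth = sim$truth)
}
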