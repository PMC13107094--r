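#' Per-segment spectral products via the zero-padded DFT
#'
#' Each channel is mean-subtracted over the analysis window, zero-padded to
#' `padded_samples`, and Fourier transformed. The periodogram products are
#' `fxx = |X|^2 / (2*pi*N)`, `fyy = |Y|^2 / (2*pi*N)` and
#' `fxy = conj(X) * Y / (2*pi*N)` with `N` the analysis length; the
#' `1/(2*pi*N)` constant is one fixed normalization convention — coherence
#' and the difference-of-coherence test are invariant to it. With this sign
#' convention a positive cumulant-density lag means channel 2 (`y`) lags
#' channel 1 (`x`). Zero padding refines the frequency grid to spacing
#' `sampling_rate / padded_samples` without adding information; the
#' underlying resolution remains `sampling_rate / analysis_samples`.
#'
#' @param segment a `trial_segment` (from [extract_segment()]) or a 2 x N
#'   numeric matrix.
#' @param padded_samples segment length after zero padding (>= N).
#' @param sampling_rate required when `segment` is a bare matrix.
#' @return list with two-sided length-`padded_samples` vectors `fxx`, `fyy`
#'   (real), `fxy` (complex), plus `analysis_samples`, `padded_samples`,
#'   `sampling_rate`.
#' @export
segment_periodogram <- function(segment, padded_samples,
                                sampling_rate = NULL) {
  if (inherits(segment, "trial_segment")) {
    if (!segment$accepted) stop("cannot transform a rejected segment")
    x <- segment$x
    sampling_rate <- segment$sampling_rate
  } else {
    x <- segment
    if (is.null(sampling_rate)) stop("sampling_rate required for bare matrices")
  }
  stopifnot(is.matrix(x), nrow(x) == 2L)
  n <- ncol(x)
  if (n == 0L) stop("empty segment")
  padded_samples <- as.integer(padded_samples)
  stopifnot(padded_samples >= n)
  pad <- function(v) c(v - mean(v), rep(0, padded_samples - n))
  X <- stats::fft(pad(x[1L, ]))
  Y <- stats::fft(pad(x[2L, ]))
  norm <- 1 / (2 * pi * n)
  list(fxx = Re(X * Conj(X)) * norm,
       fyy = Re(Y * Conj(Y)) * norm,
       fxy = Conj(X) * Y * norm,
       analysis_samples = n,
       padded_samples = padded_samples,
       sampling_rate = sampling_rate)
}

#' Average periodograms over segments into a spectral matrix
#'
#' Auto- and cross-spectra are estimated by averaging the per-segment
#' periodogram products over `L` disjoint segments (one per trial, matching
#' the independence assumption behind the confidence limit).
#'
#' @param segments list of accepted `trial_segment`s with a common geometry,
#'   or a pre-computed list of [segment_periodogram()] results.
#' @param padded_samples zero-padded length; defaults to the startle/other
#'   convention of twice the analysis length.
#' @return an object of class `spectral_matrix`: positive-half `freq` grid
#'   (Hz, 0 to Nyquist), full two-sided `fxx`, `fyy`, `fxy`, the segment
#'   count `L`, and the geometry fields.
#' @export
estimate_spectra <- function(segments, padded_samples = NULL) {
  stopifnot(length(segments) >= 1L)
  if (inherits(segments[[1L]], "trial_segment")) {
    lens <- vapply(segments, function(s) s$analysis_samples, integer(1))
    if (length(unique(lens)) != 1L) stop("mixed segment lengths")
    if (is.null(padded_samples)) padded_samples <- 2L * lens[1L]
    periodograms <- lapply(segments, segment_periodogram, padded_samples)
  } else {
    periodograms <- segments
  }
  p1 <- periodograms[[1L]]
  same <- vapply(periodograms, function(p) {
    p$analysis_samples == p1$analysis_samples &&
      p$padded_samples == p1$padded_samples &&
      p$sampling_rate == p1$sampling_rate
  }, logical(1))
  if (!all(same)) stop("mixed segment geometries")
  L <- length(periodograms)
  add <- function(field) Reduce(`+`, lapply(periodograms, `[[`, field)) / L
  new_spectral_matrix(add("fxx"), add("fyy"), add("fxy"), L,
                      p1$analysis_samples, p1$padded_samples, p1$sampling_rate)
}

new_spectral_matrix <- function(fxx, fyy, fxy, L, analysis_samples,
                                padded_samples, sampling_rate) {
  P <- padded_samples
  freq <- (0:(P %/% 2)) * sampling_rate / P
  structure(list(freq = freq, fxx = fxx, fyy = fyy, fxy = fxy, L = L,
                 analysis_samples = analysis_samples,
                 padded_samples = P, sampling_rate = sampling_rate),
            class = "spectral_matrix")
}

#' @export
print.spectral_matrix <- function(x, ...) {
  cat(sprintf(
    "<spectral_matrix> L = %d segments, %d -> %d samples @ %g Hz (bin %.5f Hz)\n",
    x$L, x$analysis_samples, x$padded_samples, x$sampling_rate,
    x$sampling_rate / x$padded_samples))
  invisible(x)
}

#' Frequency-bin spacing of a segment geometry
#'
#' `sampling_rate / samples`: with 2000 Hz sampling this gives the standard
#' grids 3.90625 Hz (512-sample epochs), 1.953125 Hz (1024) and the
#' underlying 7.8125 Hz resolution of a 256-sample analysis window.
#'
#' @param sampling_rate Hz.
#' @param samples epoch length in samples (padded for the plotted grid,
#'   unpadded for the underlying resolution).
#' @return bin spacing in Hz.
#' @export
bin_spacing_hz <- function(sampling_rate, samples) sampling_rate / samples

positive_bins <- function(S) seq_len(S$padded_samples %/% 2 + 1L)

#' 95% confidence limit for coherence under independence
#'
#' `CL = 1 - alpha^(1/(L-1))` with `L` the number of (pooled) segments: the
#' upper `1 - alpha` quantile of the estimated coherence when the true
#' coherence is zero.
#'
#' @param L segment count (>= 2).
#' @param alpha significance level (default 0.05).
#' @return the confidence limit in (0, 1).
#' @export
confidence_limit <- function(L, alpha = 0.05) {
  if (any(L < 2)) stop("confidence limit requires L >= 2 segments")
  1 - alpha^(1 / (L - 1))
}

#' Coherence estimate from a spectral matrix
#'
#' Per-bin squared coherence `|fxy|^2 / (fxx * fyy)` on the positive
#' frequency grid, with the coherency magnitude (its square root), the
#' cross-spectral phase, and the segment-count-based 95% confidence limit.
#' Bins with zero spectral power (e.g. the mean-subtracted 0 Hz bin) get
#' coherence 0 and are flagged in `zero_power`.
#'
#' @param S a `spectral_matrix`.
#' @param alpha significance level for the confidence limit.
#' @return an object of class `coherence_estimate` with fields `freq`,
#'   `coherence`, `coherency`, `phase`, `cl`, `L`, `zero_power`, and the
#'   grid geometry.
#' @export
coherence <- function(S, alpha = 0.05) {
  stopifnot(inherits(S, "spectral_matrix"))
  if (S$L < 2) {
    warning("coherence with L < 2 segments is identically 1 and carries no information")
  }
  pb <- positive_bins(S)
  fxx <- S$fxx[pb]
  fyy <- S$fyy[pb]
  fxy <- S$fxy[pb]
  denom <- fxx * fyy
  # relative guard: bins whose power is numerically indistinguishable from 0
  # (notably the mean-subtracted 0 Hz bin) carry no coherence information
  zero_power <- denom <= max(denom) * 1e-24
  coh <- numeric(length(pb))
  coh[!zero_power] <- Mod(fxy[!zero_power])^2 / denom[!zero_power]
  cl <- if (S$L >= 2) confidence_limit(S$L, alpha) else NA_real_
  structure(list(freq = S$freq, coherence = coh,
                 coherency = sqrt(coh), phase = Arg(fxy),
                 fxx = fxx, fyy = fyy, fxy = fxy,
                 cl = cl, alpha = alpha, L = S$L,
                 zero_power = zero_power,
                 analysis_samples = S$analysis_samples,
                 padded_samples = S$padded_samples,
                 sampling_rate = S$sampling_rate),
            class = "coherence_estimate")
}

#' @export
print.coherence_estimate <- function(x, ...) {
  cat(sprintf("<coherence_estimate> %d bins (0-%.1f Hz), L = %d, 95%% CL = %.4f\n",
              length(x$freq), max(x$freq), x$L, x$cl))
  above <- sum(x$coherence > x$cl, na.rm = TRUE)
  cat(sprintf("  %d bin(s) above CL; peak %.3f at %.2f Hz\n", above,
              max(x$coherence), x$freq[which.max(x$coherence)]))
  invisible(x)
}

#' @export
as.data.frame.coherence_estimate <- function(x, ...) {
  data.frame(frequency_hz = x$freq, fxx = x$fxx, fyy = x$fyy,
             re_fxy = Re(x$fxy), im_fxy = Im(x$fxy),
             coherence = x$coherence, coherency = x$coherency,
             phase_rad = x$phase, cl = x$cl, n_segments = x$L)
}

#' Cumulant density (time-domain correlation) from a spectral matrix
#'
#' The inverse Fourier transform of the two-sided cross-spectrum, evaluated
#' on the lag grid `-padded/2 ... padded/2 - 1` samples (spacing
#' `1/sampling_rate`). A positive lag means channel 2 lags channel 1. Flat
#' confidence bounds are attached from the asymptotic variance under
#' independence, `var(q) = (2*pi/P)^2 * sum_k fxx(k)*fyy(k) / L`, using the
#' estimated autospectra.
#'
#' @param S a `spectral_matrix`.
#' @param conf bound coverage (default 0.95 giving +/- 1.96 SD).
#' @return an object of class `cumulant_density` with `lag_ms`, `q`,
#'   `upper`, `lower`, `L`.
#' @export
cumulant_density <- function(S, conf = 0.95) {
  stopifnot(inherits(S, "spectral_matrix"))
  P <- S$padded_samples
  q_raw <- stats::fft(S$fxy, inverse = TRUE) * (2 * pi / P)
  scale <- max(Mod(q_raw), .Machine$double.eps)
  if (max(abs(Im(q_raw))) / scale > 1e-10) {
    warning("cumulant density has a non-negligible imaginary residue")
  }
  q <- Re(q_raw)
  # reorder circular lags 0..P-1 to -P/2 .. P/2-1
  lag_idx <- c((P %/% 2 + 1L):P, 1L:(P %/% 2))
  q <- q[lag_idx]
  lag_ms <- ((-(P %/% 2)):(P %/% 2 - 1L)) / S$sampling_rate * 1000
  z <- stats::qnorm(1 - (1 - conf) / 2)
  v <- (2 * pi / P)^2 * sum(S$fxx * S$fyy) / S$L
  bound <- z * sqrt(v)
  structure(list(lag_ms = lag_ms, q = q, upper = bound, lower = -bound,
                 L = S$L, sampling_rate = S$sampling_rate),
            class = "cumulant_density")
}

#' @export
as.data.frame.cumulant_density <- function(x, ...) {
  data.frame(lag_ms = x$lag_ms, cumulant = x$q,
             upper_bound = x$upper, lower_bound = x$lower,
             n_segments = x$L)
}

#' @export
print.cumulant_density <- function(x, ...) {
  pk <- which.max(abs(x$q))
  cat(sprintf("<cumulant_density> lags %.1f..%.1f ms, L = %d; |q| peak at %+.2f ms\n",
              min(x$lag_ms), max(x$lag_ms), x$L, x$lag_ms[pk]))
  invisible(x)
}

#' Pool spectral estimates across records
#'
#' Default `method = "spectra"`: auto- and cross-spectra are aggregated with
#' segment-count weights, exactly equivalent to averaging the periodograms of
#' all `sum(L_i)` segments as one record; the pooled confidence limit then
#' uses the combined segment count. The alternative `method = "fisher"`
#' aggregates per-record Fisher-transformed coherency magnitudes with
#' segment-count weights and returns a pooled `coherence_estimate` directly
#' (no pooled spectra exist under that scheme).
#'
#' @param records list of `spectral_matrix` objects on identical grids.
#' @param method `"spectra"` (default) or `"fisher"`.
#' @param alpha significance level used when `method = "fisher"`.
#' @return a `spectral_matrix` (`"spectra"`) or `coherence_estimate`
#'   (`"fisher"`).
#' @export
pool_records <- function(records, method = c("spectra", "fisher"),
                         alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(length(records) >= 1L)
  r1 <- records[[1L]]
  for (r in records) {
    stopifnot(inherits(r, "spectral_matrix"))
    if (r$padded_samples != r1$padded_samples ||
        r$analysis_samples != r1$analysis_samples ||
        r$sampling_rate != r1$sampling_rate) {
      stop("cannot pool records on different frequency grids")
    }
  }
  Ls <- vapply(records, `[[`, numeric(1), "L")
  Ltot <- sum(Ls)
  if (method == "spectra") {
    wsum <- function(field) {
      Reduce(`+`, Map(function(r, L) L * r[[field]], records, Ls)) / Ltot
    }
    new_spectral_matrix(wsum("fxx"), wsum("fyy"), wsum("fxy"), Ltot,
                        r1$analysis_samples, r1$padded_samples,
                        r1$sampling_rate)
  } else {
    zs <- Map(function(r, L) L * fisher_transform(coherence(r)$coherency),
              records, Ls)
    z_pool <- Reduce(`+`, zs) / Ltot
    coh <- tanh(z_pool)^2
    pb <- seq_along(r1$freq)
    structure(list(freq = r1$freq, coherence = coh, coherency = tanh(z_pool),
                   phase = rep(NA_real_, length(coh)),
                   fxx = rep(NA_real_, length(coh)),
                   fyy = rep(NA_real_, length(coh)),
                   fxy = rep(NA_complex_, length(coh)),
                   cl = confidence_limit(Ltot, alpha), alpha = alpha,
                   L = Ltot, zero_power = rep(FALSE, length(coh)),
                   analysis_samples = r1$analysis_samples,
                   padded_samples = r1$padded_samples,
                   sampling_rate = r1$sampling_rate),
              class = "coherence_estimate")
  }
}

#' Crosstalk diagnostic on a coherence/cumulant pair
#'
#' Electrode crosstalk mixes the two signals instantaneously, producing (a) a
#' narrow cumulant-density peak at zero lag and (b) significant broadband
#' coherence. The flag is raised only when both components hold: the global
#' `|q|` maximum lies within `central_window_ms` of lag 0 and exceeds the
#' independence bounds, and more than `broadband_fraction` of the bins up to
#' `broadband_max_hz` (excluding the 0 Hz bin) exceed the confidence limit.
#' A genuine narrowband common drive fails the breadth test and is not
#' flagged.
#'
#' @param C a `coherence_estimate`.
#' @param Q the matching `cumulant_density`.
#' @param central_window_ms half-width of the zero-lag window (ms).
#' @param broadband_fraction fraction of low-frequency bins that must exceed
#'   the CL (default 0.5).
#' @param broadband_max_hz upper edge of the band checked for breadth.
#' @return list: `flag` (logical), `central_peak`, `broadband`,
#'   `peak_lag_ms`, `frac_above_cl`.
#' @export
crosstalk_flag <- function(C, Q, central_window_ms = 2,
                           broadband_fraction = 0.5, broadband_max_hz = 100) {
  stopifnot(inherits(C, "coherence_estimate"), inherits(Q, "cumulant_density"))
  pk <- which.max(abs(Q$q))
  peak_lag <- Q$lag_ms[pk]
  central <- abs(peak_lag) <= central_window_ms && abs(Q$q[pk]) > Q$upper
  bins <- which(C$freq > 0 & C$freq <= broadband_max_hz)
  frac <- mean(C$coherence[bins] > C$cl)
  broadband <- frac > broadband_fraction
  list(flag = central && broadband, central_peak = central,
       broadband = broadband, peak_lag_ms = peak_lag, frac_above_cl = frac)
}
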