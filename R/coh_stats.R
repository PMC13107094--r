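#' Variance-stabilizing Fisher transform of coherency magnitudes
#'
#' `z = atanh(|R|)` applied per bin to the magnitude of coherency (the square
#' root of the plotted coherence). Values at or above 1 — possible only
#' through degeneracy such as a single-segment estimate — are clipped to
#' `1 - 1e-12` and flagged via `attr(, "clipped")`.
#'
#' @param r numeric vector of coherency magnitudes in `[0, 1]`.
#' @return numeric vector of transformed values; attribute `clipped` marks
#'   any clipped entries.
#' @export
fisher_transform <- function(r) {
  if (any(r < 0)) stop("coherency magnitudes must be non-negative")
  clipped <- r >= 1
  r[clipped] <- 1 - 1e-12
  z <- atanh(r)
  if (any(clipped)) attr(z, "clipped") <- which(clipped)
  z
}

#' Chi-squared extended difference-of-coherence test
#'
#' Compares coherence across `k >= 2` groups at every frequency bin. With
#' `z_i = atanh(|R_i|)` the Fisher-transformed coherency of group `i`
#' estimated from `L_i` segments, the per-bin statistic is
#'
#' `chi2 = 2 * (sum_i L_i z_i^2 - (sum_i L_i z_i)^2 / sum_i L_i)`
#'
#' which under equal coherence across groups is asymptotically chi-squared
#' with `k - 1` degrees of freedom. A bin is significant when the statistic
#' exceeds the upper-`alpha` quantile of that distribution. No correction is
#' applied across frequency bins by default; `bonferroni = TRUE` divides
#' `alpha` by the bin count.
#'
#' @param groups list of `coherence_estimate`s on identical frequency grids
#'   (each carries its own segment count `L`).
#' @param alpha significance level (default 0.05).
#' @param bonferroni correct the threshold across bins (default `FALSE`).
#' @return an object of class `doc_test` with `freq`, `chi2`, `threshold`,
#'   `significant`, `k`, `df`, `alpha`.
#' @export
doc_test <- function(groups, alpha = 0.05, bonferroni = FALSE) {
  k <- length(groups)
  if (k < 2L) stop("difference-of-coherence test needs at least 2 groups")
  f1 <- groups[[1L]]$freq
  for (g in groups) {
    stopifnot(inherits(g, "coherence_estimate"))
    if (length(g$freq) != length(f1) || any(g$freq != f1)) {
      stop("groups are on different frequency grids")
    }
  }
  Ls <- vapply(groups, `[[`, numeric(1), "L")
  Z <- vapply(groups, function(g) as.numeric(fisher_transform(g$coherency)),
              numeric(length(f1)))
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1L)  # single-bin grids
  sum_Lz2 <- drop(Z^2 %*% Ls)
  sum_Lz <- drop(Z %*% Ls)
  chi2 <- 2 * (sum_Lz2 - sum_Lz^2 / sum(Ls))
  chi2 <- pmax(chi2, 0)  # guard tiny negative rounding
  a <- if (bonferroni) alpha / length(f1) else alpha
  threshold <- stats::qchisq(1 - a, df = k - 1L)
  structure(list(freq = f1, chi2 = chi2, threshold = threshold,
                 significant = chi2 > threshold, k = k, df = k - 1L,
                 alpha = alpha, bonferroni = bonferroni, L = Ls),
            class = "doc_test")
}

#' @export
as.data.frame.doc_test <- function(x, ...) {
  data.frame(frequency_hz = x$freq, chi2 = x$chi2, threshold = x$threshold,
             significant = x$significant)
}

#' @export
print.doc_test <- function(x, ...) {
  cat(sprintf(
    "<doc_test> k = %d groups (L: %s), df = %d, threshold chi2 = %.3f\n",
    x$k, paste(x$L, collapse = ", "), x$df, x$threshold))
  sig <- which(x$significant)
  if (length(sig)) {
    cat("  significant bins (Hz):",
        paste(round(x$freq[sig], 1), collapse = ", "), "\n")
  } else cat("  no significant bins\n")
  invisible(x)
}

#' Resolve a frequency band onto a grid
#'
#' Returns the inclusive set of bins whose frequency, rounded to 0.1 Hz
#' (the precision at which band edges are conventionally stated), lies in
#' `[lower_hz, upper_hz]`.
#'
#' @param lower_hz,upper_hz band edges in Hz (`lower < upper`).
#' @param freq numeric frequency grid (Hz), e.g. `estimate$freq`.
#' @param name band label.
#' @return object of class `band_definition`: `name`, `lower_hz`, `upper_hz`,
#'   `bins` (indices into `freq`), `bin_freqs_hz`.
#' @export
resolve_band <- function(lower_hz, upper_hz, freq, name = "band") {
  stopifnot(lower_hz < upper_hz)
  if (upper_hz > max(freq)) stop("band extends beyond the Nyquist grid")
  fr <- round(freq, 1)
  bins <- which(fr >= lower_hz & fr <= upper_hz)
  if (!length(bins)) stop("band resolves to an empty bin set on this grid")
  structure(list(name = name, lower_hz = lower_hz, upper_hz = upper_hz,
                 bins = bins, bin_freqs_hz = freq[bins]),
            class = "band_definition")
}

#' Standard high-alpha and beta band presets
#'
#' Band edges depend on the segment geometry through the frequency grid: the
#' startle configuration (256-sample windows) uses high alpha 11.7-15.6 Hz
#' and beta 19.5-31.3 Hz; all other tasks (512-sample windows) use high
#' alpha 9.8-15.6 Hz and beta 17.6-31.2 Hz.
#'
#' @param task `"startle"` or any of the longer-window tasks.
#' @return named list of `c(lower, upper)` edges: `high_alpha`, `beta`.
#' @export
band_preset <- function(task = c("startle", "startreact", "perturbation",
                                 "balance", "ankle")) {
  task <- match.arg(task)
  if (task == "startle") {
    list(high_alpha = c(11.7, 15.6), beta = c(19.5, 31.3))
  } else {
    list(high_alpha = c(9.8, 15.6), beta = c(17.6, 31.2))
  }
}

#' Mean coherence over a frequency band
#'
#' Adds the per-bin values over the band's bins and divides by the bin count.
#' With `transform = TRUE` (default) each bin contributes its
#' Fisher-transformed coherency magnitude `atanh(|R|)`, the
#' variance-stabilized quantity used for band-level summaries; with
#' `transform = FALSE` the raw coherence values are averaged.
#'
#' @param C a `coherence_estimate`.
#' @param band a `band_definition` resolved on `C`'s grid.
#' @param transform apply the Fisher transform per bin before averaging.
#' @return numeric scalar.
#' @export
band_mean <- function(C, band, transform = TRUE) {
  stopifnot(inherits(C, "coherence_estimate"),
            inherits(band, "band_definition"))
  if (max(band$bins) > length(C$freq)) stop("band not resolved on this grid")
  vals <- if (transform) as.numeric(fisher_transform(C$coherency[band$bins]))
          else C$coherence[band$bins]
  sum(vals) / length(vals)
}
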