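test_that("zero padding yields the printed frequency grids", {
  set.seed(1)
  pg <- segment_periodogram(matrix(rnorm(512), 2), 512, 2000)
  S <- estimate_spectra(list(pg))
  expect_equal(length(S$freq), 257)          # 0 Hz + 256 positive bins
  expect_equal(diff(S$freq)[1], 3.90625)
  expect_equal(max(S$freq), 1000)            # Nyquist
  p2 <- estimate_spectra(list(segment_periodogram(matrix(rnorm(1024), 2),
                                                  1024, 2000)))
  expect_equal(diff(p2$freq)[1], 1.953125)
})

test_that("a pure tone segment concentrates power at the nearest bin", {
  fs <- 2000
  t <- (0:255) / fs
  x <- sin(2 * pi * 12 * t)
  pg <- segment_periodogram(rbind(x, x), 512, fs)
  S <- estimate_spectra(list(pg))
  use <- which(S$freq > 0)
  expect_equal(use[which.max(S$fxx[use])],
               which.min(abs(S$freq - 12)))
})

test_that("zero and constant segments transform to zero products", {
  pg <- segment_periodogram(matrix(0, 2, 64), 128, 2000)
  expect_true(all(pg$fxx == 0))
  expect_true(all(Mod(pg$fxy) == 0))
  # constant segments are zero after mean subtraction
  pg2 <- segment_periodogram(matrix(3, 2, 64), 128, 2000)
  expect_true(all(pg2$fxx == 0))
})

test_that("averaged spectra match the brute-force two-loop oracle", {
  set.seed(2)
  mats <- lapply(1:3, function(i) matrix(rnorm(2 * 32), 2))
  S <- estimate_spectra(lapply(mats, segment_periodogram, 64, 2000))
  oracle <- oracle_spectra(mats, 64, 2000)
  expect_equal(S$fxx, oracle$fxx, tolerance = 1e-12)
  expect_equal(S$fyy, oracle$fyy, tolerance = 1e-12)
  expect_equal(S$fxy, oracle$fxy, tolerance = 1e-12)
  C <- coherence(S)
  pb <- seq_along(C$freq)
  oracle_coh <- Mod(oracle$fxy[pb])^2 / (oracle$fxx[pb] * oracle$fyy[pb])
  expect_equal(C$coherence[!C$zero_power], oracle_coh[!C$zero_power],
               tolerance = 1e-12)
})

test_that("single-segment coherence is identically 1 where power exists", {
  set.seed(3)
  S <- estimate_spectra(list(segment_periodogram(matrix(rnorm(128), 2),
                                                 256, 2000)))
  expect_warning(C <- coherence(S), "L < 2")
  expect_equal(C$coherence[!C$zero_power],
               rep(1, sum(!C$zero_power)), tolerance = 1e-9)
  # averaging identical copies changes nothing
  pg <- segment_periodogram(matrix(rnorm(128), 2), 256, 2000)
  S1 <- estimate_spectra(list(pg))
  S3 <- estimate_spectra(list(pg, pg, pg))
  expect_equal(S1$fxy, S3$fxy)
  expect_equal(S3$L, 3L)
})

test_that("coherence of a channel with itself is 1 and respects its bounds", {
  set.seed(4)
  segs <- lapply(1:8, function(i) {
    x <- rnorm(256)
    segment_periodogram(rbind(x, x), 512, 2000)
  })
  C <- coherence(estimate_spectra(segs))
  expect_equal(C$coherence[!C$zero_power],
               rep(1, sum(!C$zero_power)), tolerance = 1e-9)

  # Cauchy-Schwarz and [0, 1] range on random independent data
  for (i in 1:5) {
    S <- estimate_spectra(white_periodograms(6))
    expect_true(all(Mod(S$fxy)^2 <= S$fxx * S$fyy + 1e-12))
    Ci <- coherence(S)
    expect_true(all(Ci$coherence >= 0 & Ci$coherence <= 1 + 1e-12))
  }
})

test_that("coherence is invariant under per-channel rescaling", {
  set.seed(6)
  mats <- lapply(1:5, function(i) matrix(rnorm(2 * 128), 2))
  C1 <- coherence(estimate_spectra(lapply(mats, segment_periodogram, 256, 2000)))
  scaled <- lapply(mats, function(m) rbind(3.7 * m[1, ], 0.2 * m[2, ]))
  C2 <- coherence(estimate_spectra(lapply(scaled, segment_periodogram, 256, 2000)))
  keep <- !C1$zero_power & !C2$zero_power
  expect_equal(C1$coherence[keep], C2$coherence[keep], tolerance = 1e-12)
})

test_that("zero padding preserves band-integrated power (Parseval)", {
  set.seed(7)
  m <- matrix(rnorm(2 * 256), 2)
  unpadded <- segment_periodogram(m, 256, 2000)
  padded <- segment_periodogram(m, 512, 2000)
  pow_unpadded <- sum(unpadded$fxx) * 2000 / 256
  pow_padded <- sum(padded$fxx) * 2000 / 512
  expect_equal(pow_padded, pow_unpadded, tolerance = 1e-9)
})

test_that("the confidence limit follows 1 - alpha^(1/(L-1))", {
  expect_equal(confidence_limit(2), 0.95)
  expect_equal(confidence_limit(141), 1 - 0.05^(1 / 140), tolerance = 1e-15)
  Ls <- c(2, 5, 20, 141, 500)
  expect_true(all(diff(confidence_limit(Ls)) < 0))
  expect_error(confidence_limit(1), "L >= 2")
})

test_that("cumulant density is real with the correct lag conventions", {
  set.seed(8)
  # autocase: global maximum at zero lag
  segs <- lapply(1:10, function(i) {
    x <- rnorm(256)
    segment_periodogram(rbind(x, x), 512, 2000)
  })
  Q <- cumulant_density(estimate_spectra(segs))
  expect_equal(Q$lag_ms[which.max(Q$q)], 0)
  expect_equal(length(Q$lag_ms), 512)
  expect_equal(diff(Q$lag_ms)[1], 0.5)  # 1/sampling_rate in ms

  # y delayed by 10 ms (20 samples) -> peak at +10 ms
  d <- 20
  segs2 <- lapply(1:10, function(i) {
    x <- rnorm(300)
    segment_periodogram(rbind(x[1:256], c(rep(0, d), x)[1:256]), 512, 2000)
  })
  Q2 <- cumulant_density(estimate_spectra(segs2))
  expect_equal(Q2$lag_ms[which.max(abs(Q2$q))], 10)

  # independence: |q| within bounds at >= 95% of lags (pooled over runs)
  inside <- logical(0)
  for (i in 1:5) {
    Qi <- cumulant_density(estimate_spectra(white_periodograms(50, 256)))
    inside <- c(inside, abs(Qi$q) <= Qi$upper)
  }
  expect_gte(mean(inside), 0.95 - 0.02)
})

test_that("pooling is exactly averaging the concatenated segment list", {
  set.seed(10)
  mats <- lapply(1:9, function(i) matrix(rnorm(2 * 128), 2))
  pgs <- lapply(mats, segment_periodogram, 256, 2000)
  rec1 <- estimate_spectra(pgs[1:2])
  rec2 <- estimate_spectra(pgs[3:5])
  rec3 <- estimate_spectra(pgs[6:9])
  pooled <- pool_records(list(rec1, rec2, rec3))
  all_at_once <- estimate_spectra(pgs)
  expect_equal(pooled$fxx, all_at_once$fxx, tolerance = 1e-14)
  expect_equal(pooled$fxy, all_at_once$fxy, tolerance = 1e-14)
  expect_equal(pooled$L, 9L)

  # pooling one record is the identity
  expect_equal(pool_records(list(rec2)), rec2)

  # k identical records: same coherence, CL at k*L
  pooled_k <- pool_records(list(rec1, rec1, rec1))
  expect_equal(coherence(pooled_k)$coherence, coherence(rec1)$coherence)
  expect_equal(coherence(pooled_k)$cl, confidence_limit(6))

  # grid mismatch rejected
  other <- estimate_spectra(list(segment_periodogram(mats[[1]], 512, 2000)))
  expect_error(pool_records(list(rec1, other)), "grids")

  # Fisher-pooling alternative returns a pooled estimate at the combined L
  fp <- pool_records(list(rec1, rec2), method = "fisher")
  expect_s3_class(fp, "coherence_estimate")
  expect_equal(fp$L, 5)
})

test_that("crosstalk is flagged only with a central peak plus broadband coherence", {
  # mixed channels: both signatures present
  rec <- stationary_pair(60, seed = 51, crosstalk = 0.4)
  S <- estimate_spectra(cut_segments(rec, 256, 60), 512)
  flag_mixed <- crosstalk_flag(coherence(S), cumulant_density(S))
  expect_true(flag_mixed$flag)
  expect_true(flag_mixed$central_peak)
  expect_true(flag_mixed$broadband)

  # independent channels: no broadband coherence
  rec2 <- stationary_pair(60, seed = 52)
  S2 <- estimate_spectra(cut_segments(rec2, 256, 60), 512)
  flag_ind <- crosstalk_flag(coherence(S2), cumulant_density(S2))
  expect_false(flag_ind$flag)

  # narrowband common drive: coherent but not broadband
  rec3 <- stationary_pair(60, seed = 53, common_drive = list(c(12, 0.5)))
  S3 <- estimate_spectra(cut_segments(rec3, 256, 60), 512)
  flag_nb <- crosstalk_flag(coherence(S3), cumulant_density(S3))
  expect_false(flag_nb$flag)
  expect_false(flag_nb$broadband)
})
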