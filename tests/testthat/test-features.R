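# Hand-computed DFT oracle: x = [1, 0, -1, 0] at fs = 4 Hz has
# X(1 Hz) = 1 - (-1)(-1)... = sum x[n] exp(-2*pi*i*n/4) = 1 + 1 = 2,
# so |X|^2 = 4 concentrated at the 1 Hz bin.
test_that("spectrum matches the hand DFT on small signals", {
  sp <- compute_spectrum(c(0, 0, 0, 0), fs = 4)
  expect_equal(sp$power, rep(0, 3))
  expect_equal(sp$frequencies, c(0, 1, 2))

  sp <- compute_spectrum(c(1, 0, -1, 0), fs = 4)
  expect_equal(sp$power, c(0, 4, 0), tolerance = 1e-12)

  sp <- compute_spectrum(rep(2.5, 8), fs = 8)
  expect_equal(sp$power[1], (2.5 * 8)^2, tolerance = 1e-12)
  expect_equal(sp$power[-1], rep(0, 4), tolerance = 1e-9)

  expect_error(compute_spectrum(1, fs = 4), "2 samples")
  expect_error(compute_spectrum(c(1, 2), fs = 0), "positive")
})

test_that("band power sums inclusively over bins inside the limits", {
  sp <- compute_spectrum(c(1, 0, -1, 0), fs = 4)
  expect_equal(band_power(sp, band_definition("b", 0.5, 1.5)), 4,
               tolerance = 1e-12)
  expect_equal(band_power(compute_spectrum(rep(0, 16), 125),
                          band_definition("alpha", 8, 13)), 0)
  # empty band interval between bins
  expect_equal(band_power(sp, band_definition("none", 1.2, 1.8)), 0)
})

test_that("a pure alpha sinusoid concentrates its non-DC power in alpha", {
  t <- (0:249) / 125
  sp <- compute_spectrum(sin(2 * pi * 10 * t), fs = 125)
  total_nondc <- sum(sp$power[sp$frequencies > 0])
  alpha <- band_power(sp, band_definition("alpha", 8, 13))
  expect_gte(alpha, 0.99 * total_nondc)
})

test_that("dominant frequency picks the strongest rhythm, DC excluded", {
  t <- (0:124) / 125
  expect_equal(dominant_frequency(compute_spectrum(sin(2 * pi * 10 * t), 125)),
               10)
  t2 <- (0:249) / 125
  x <- 2 * sin(2 * pi * 8 * t2) + sin(2 * pi * 20 * t2)
  expect_equal(dominant_frequency(compute_spectrum(x, 125)), 8)
  expect_error(dominant_frequency(compute_spectrum(rep(3, 64), 125)),
               "undefined")
  # tie broken toward the lower frequency
  tie <- structure(list(frequencies = c(0, 1, 2, 3), power = c(9, 5, 5, 1)),
                   class = "eeg_spectrum")
  expect_equal(dominant_frequency(tie), 1)
})

test_that("amplitude statistics follow their defining identities", {
  expect_equal(mean_amplitude(c(0, 0, 0)), 0)
  expect_equal(mean_amplitude(c(1, -1, 2)), 4 / 3)
  expect_equal(mean_amplitude(-5), 5)

  expect_equal(std_amplitude(c(1, -1)), 0)
  expect_equal(std_amplitude(c(0, 2)), 1)
  expect_equal(std_amplitude(7), 0)

  expect_equal(median_amplitude(c(3, 1, 2)), 2)
  expect_equal(median_amplitude(c(1, 2, 3, 4)), 2.5)
  expect_equal(median_amplitude(c(-3, -1, -2)), -2)  # signed, not rectified

  expect_equal(ptp_amplitude(c(4, 4, 4)), 0)
  expect_equal(ptp_amplitude(c(-2, 5)), 7)
  expect_equal(ptp_amplitude(c(0, 1, -1, 0.5)), 2)

  expect_error(mean_amplitude(numeric(0)), "empty")
})

test_that("feature vectors have the documented length, order and names", {
  set.seed(11)
  tr16 <- eeg_trial(matrix(rnorm(500 * 16), 500, 16), 125)
  v <- extract_features(tr16)
  expect_length(v, 160L)
  expect_equal(names(v)[1:10],
               paste0("ch1_", c("power_delta", "power_theta", "power_alpha",
                                "power_beta", "power_gamma", "dominant_freq",
                                "mean_amp", "std_amp", "median_amp", "ptp_amp")))

  t <- (0:499) / 125
  tr1 <- eeg_trial(matrix(1.5 * sin(2 * pi * 10 * t), ncol = 1), 125)
  v1 <- extract_features(tr1)
  expect_equal(unname(v1["ch1_dominant_freq"]), 10)
  # sampling at 12.5 points/cycle misses the analog extremum by up to
  # 1 - cos(pi/12.5) ~ 3%; twice the amplitude within that tolerance
  expect_equal(unname(v1["ch1_ptp_amp"]), 3, tolerance = 0.01)

  silent <- eeg_trial(matrix(0, 100, 2), 125)
  expect_error(extract_features(silent), "ch1")
})

test_that("band powers are additive over a partition of the positive bins", {
  set.seed(12)
  sp <- compute_spectrum(rnorm(200), fs = 100)
  # three bands that tile (0, 50] without sharing a bin
  cuts <- list(c(0.25, 16.75), c(16.76, 33.75), c(33.76, 50))
  parts <- vapply(cuts, function(cc)
    band_power(sp, band_definition("p", cc[1], cc[2])), numeric(1))
  expect_equal(sum(parts), sum(sp$power[sp$frequencies > 0]),
               tolerance = 1e-9)
})

test_that("a shared band boundary bin is counted in both adjacent bands", {
  # 4 Hz is both the delta upper and theta lower limit
  t <- (0:124) / 125
  sp <- compute_spectrum(sin(2 * pi * 4 * t), fs = 125)
  bp_delta <- band_power(sp, band_definition("delta", 0.5, 4))
  bp_theta <- band_power(sp, band_definition("theta", 4, 8))
  expect_gt(bp_delta, 0)
  expect_equal(bp_delta, bp_theta, tolerance = 1e-9)
})

test_that("features scale and shift the way their formulas dictate", {
  set.seed(13)
  x <- rnorm(128)
  c0 <- 2.5
  sp1 <- compute_spectrum(x, 64)
  sp2 <- compute_spectrum(c0 * x, 64)
  expect_equal(sp2$power, c0^2 * sp1$power, tolerance = 1e-9)
  expect_equal(dominant_frequency(sp1), dominant_frequency(sp2))
  expect_equal(mean_amplitude(c0 * x), c0 * mean_amplitude(x))
  expect_equal(std_amplitude(c0 * x), c0 * std_amplitude(x))
  expect_equal(ptp_amplitude(c0 * x), c0 * ptp_amplitude(x))
  # rectified statistics are not shift-invariant; ptp is
  expect_equal(ptp_amplitude(x + 10), ptp_amplitude(x))
  expect_false(isTRUE(all.equal(mean_amplitude(x + 10), mean_amplitude(x))))
})

test_that("feature extraction is channel permutation-equivariant", {
  set.seed(14)
  m <- matrix(rnorm(250 * 4), 250, 4)
  tr <- eeg_trial(m, 125, channel_names = c("a", "b", "c", "d"))
  perm <- c(3L, 1L, 4L, 2L)
  trp <- eeg_trial(m[, perm], 125, channel_names = c("a", "b", "c", "d")[perm])
  v <- matrix(extract_features(tr), nrow = 4, byrow = TRUE)
  vp <- matrix(extract_features(trp), nrow = 4, byrow = TRUE)
  expect_equal(vp, v[perm, ])
})

test_that("feature group columns tile the 160-feature layout", {
  fr <- feature_group_columns("frequency", 16)
  tm <- feature_group_columns("time", 16)
  al <- feature_group_columns("all", 16)
  expect_length(fr, 96L)
  expect_length(tm, 64L)
  expect_equal(sort(c(fr, tm)), sort(al))
  expect_equal(sort(al), 1:160)
  expect_error(feature_group_columns("wavelet", 16), "unknown")
})
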