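rate <- 256
tgrid <- (0:1279) / rate

test_that("power spectrum concentrates tones, obeys Parseval, zeroes on zeros", {
  x <- sin(2 * pi * 10 * tgrid)
  sp <- power_spectrum(x, rate)
  expect_lte(sp$df, 0.5)
  near <- abs(sp$freq - 10) <= 1
  expect_gte(sum(sp$power[near]) / sum(sp$power), 0.9)
  expect_lt(abs(sum(sp$power) * sp$df - stats::var(x)) / stats::var(x), 0.05)
  expect_true(all(power_spectrum(rep(2, 1280), rate)$power == 0))
})

test_that("relative band power isolates a 10 Hz tone into alpha", {
  sp <- power_spectrum(sin(2 * pi * 10 * tgrid), rate)
  expect_gte(relative_band_power(sp, c(8, 13)), 0.95)
  expect_lte(relative_band_power(sp, c(0.5, 4)), 0.02)
  expect_equal(relative_band_power(sp, c(0.5, 128), c(0.5, 128)), 1.0)
})

test_that("the eight band fractions of white noise sum to the band-coverage ratio", {
  set.seed(11)
  b <- eeg_bands()
  sums <- replicate(200, {
    sp <- power_spectrum(rnorm(1280), rate)
    sum(vapply(seq_len(nrow(b)), function(i) {
      relative_band_power(sp, c(b$low[i], b$high[i]))
    }, 0))
  })
  # covered bandwidth 115.5 Hz of the 127.5 Hz total
  expect_lt(abs(mean(sums) - 115.5 / 127.5), 0.02)
  expect_true(all(sums >= 0 & sums < 1))
})

test_that("band ratio follows the eps-guarded quotient", {
  expect_equal(band_ratio(0.4, 0.2), 2, tolerance = 1e-9)
  expect_equal(band_ratio(0, 0.5), 0)
  expect_true(is.finite(band_ratio(0.3, 0)))
  expect_equal(band_ratio(0.3, 0), 0.3 / 1e-12)
})

test_that("spectral edge matches cumulative-power oracles", {
  sp <- power_spectrum(sin(2 * pi * 10 * tgrid), rate)
  for (p in c(0.25, 0.5, 0.9)) {
    expect_equal(spectral_edge(sp, p)$edge_frequency, 10, tolerance = 1)
  }
  two <- sin(2 * pi * 5 * tgrid) + sin(2 * pi * 20 * tgrid)
  e <- spectral_edge(power_spectrum(two, rate), 0.5)
  expect_lte(e$edge_frequency, 6)   # half the mass already at the 5 Hz line
  set.seed(3)
  edges <- replicate(200,
    spectral_edge(power_spectrum(rnorm(1280), rate), 0.5)$edge_frequency)
  expect_lt(abs(mean(edges) - (0.5 + 100) / 2), 2)
})

test_that("summary spectral features recover tone frequencies and scaling", {
  x <- sin(2 * pi * 10 * tgrid)
  s1 <- summary_spectral_features(power_spectrum(x, rate))
  expect_equal(s1$alpha_peak, 10, tolerance = 0.5)
  expect_equal(s1$mean_frequency, 10, tolerance = 0.5)
  mix <- sin(2 * pi * 4 * tgrid) + sin(2 * pi * 16 * tgrid)
  s2 <- summary_spectral_features(power_spectrum(mix, rate))
  expect_equal(s2$mean_frequency, 10, tolerance = 0.5)
  s3 <- summary_spectral_features(power_spectrum(2 * x, rate))
  expect_equal(s3$total_power / s1$total_power, 4, tolerance = 0.01)
  expect_equal(s3$alpha_peak, s1$alpha_peak)
})

test_that("wavelet energies are zero on zeros, quadratic in scale, energy-preserving", {
  expect_equal(as.numeric(wavelet_energies(rep(0, 1280))), rep(0, 5))
  set.seed(5)
  x <- rnorm(1280)
  e1 <- wavelet_energies(x)
  e3 <- wavelet_energies(3 * x)
  expect_equal(as.numeric(e3 / e1), rep(9, 5), tolerance = 1e-9)
  expect_equal(sum(e1) + attr(e1, "approx_energy"), sum(x^2),
               tolerance = 1e-9)
  expect_error(wavelet_energies(rnorm(16)), "short")
})

test_that("statistical moments follow documented conventions", {
  m <- statistical_moments(rep(5, 100))
  expect_equal(m$mean, 5)
  expect_equal(m$variance, 0)
  expect_true(is.na(m$skewness) && is.na(m$kurtosis))
  # alternating two-point signal: skewness 0, (non-excess) kurtosis 1
  m2 <- statistical_moments(rep(c(-1, 1), 640))
  expect_equal(m2$skewness, 0, tolerance = 1e-12)
  expect_equal(m2$kurtosis, 1, tolerance = 1e-3)
  set.seed(9)
  sk <- ku <- numeric(20)
  for (i in 1:20) {
    g <- statistical_moments(rnorm(1280))
    sk[i] <- g$skewness; ku[i] <- g$kurtosis
  }
  expect_lt(abs(mean(sk)), 0.2)
  expect_lt(abs(mean(ku) - 3), 0.5)
})

test_that("Hjorth parameters match closed-form expectations", {
  h <- hjorth_parameters(rep(2, 100))
  expect_equal(h$activity, 0)
  expect_true(is.na(h$mobility))
  set.seed(13)
  mob <- replicate(20, hjorth_parameters(rnorm(1280))$mobility)
  expect_lt(abs(mean(mob) - sqrt(2)), 0.05)
  cx <- sapply(seq(0, 2 * pi, length.out = 11), function(ph) {
    hjorth_parameters(sin(2 * pi * 10 * tgrid + ph))$complexity
  })
  expect_lt(abs(mean(cx) - 1), 0.05)
})

test_that("decorrelation time matches analytic lags and orders AR processes", {
  set.seed(17)
  hits <- mean(replicate(50, decorrelation_time(rnorm(1280), rate)) ==
                 1 / rate)
  expect_gt(hits, 0.9)
  f <- 10
  dt <- decorrelation_time(sin(2 * pi * f * tgrid), rate)
  expect_lt(abs(dt - acos(exp(-1)) / (2 * pi * f)), 1 / rate)
  wn <- decorrelation_time(rnorm(1280), rate)
  ar <- decorrelation_time(as.numeric(arima.sim(list(ar = 0.99), 1280)), rate)
  expect_gt(ar, wn)
  expect_true(is.na(decorrelation_time(rep(1, 1280), rate)))
})

test_that("the default registry holds exactly 59 uniquely named features", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 59)
  expect_false(anyDuplicated(reg$name) > 0)
  expect_equal(sum(reg$kind == "ratio"), 28)
  expect_equal(sum(reg$kind == "relpow"), 8)
  expect_equal(sum(reg$kind %in% c("edge_freq", "edge_power")), 7)
})

test_that("extract_features is deterministic, channel-equivariant, and well-shaped", {
  set.seed(21)
  sig <- matrix(rnorm(2 * 3 * 1280), nrow = 2)
  ep <- segment_epochs(recording(sig, rate, c("A", "B")), 5)
  fm <- extract_features(ep)
  expect_equal(dim(fm$values), c(3, 2 * 59))
  expect_true(all(fm$valid_mask))
  # determinism
  expect_identical(extract_features(ep)$values, fm$values)
  # channel permutation equivariance
  ep2 <- segment_epochs(recording(sig[2:1, ], rate, c("B", "A")), 5)
  fm2 <- extract_features(ep2)
  expect_equal(unname(fm2$values[, 1:59]), unname(fm$values[, 60:118]))
  # duplicated epochs give identical rows
  sig3 <- cbind(sig[, 1:1280], sig[, 1:1280])
  fm3 <- extract_features(segment_epochs(recording(sig3, rate, c("A", "B")), 5))
  expect_equal(fm3$values[1, ], fm3$values[2, ])
  expect_error(extract_features(ep, registry = feature_registry()[1:10, ]),
               "59")
})

test_that("DC offsets move only the offset-sensitive features", {
  set.seed(23)
  x <- rnorm(1280)
  ep <- function(v) segment_epochs(recording(matrix(v, 1), rate, "A"), 5)
  a <- extract_features(ep(x))$values[1, ]
  b <- extract_features(ep(x + 100))$values[1, ]
  reg <- feature_registry()
  # spectra are computed on mean-removed epochs; Hjorth/variance on diffs
  insensitive <- !(reg$name %in% c("moment_mean", "wavelet_D1", "wavelet_D2",
                                   "wavelet_D3", "wavelet_D4", "wavelet_D5"))
  expect_equal(unname(a[insensitive]), unname(b[insensitive]),
               tolerance = 1e-6)
  expect_equal(unname(b["A.moment_mean"] - a["A.moment_mean"]), 100,
               tolerance = 1e-9)
})
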