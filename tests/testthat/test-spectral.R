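test_that("Welch estimates conserve variance and localize tones", {
  set.seed(1)
  fs <- 250
  x <- rnorm(2^17)
  sp <- welch_psd(x, fs)
  df <- sp$freqs[2] - sp$freqs[1]
  expect_lt(abs(sum(sp$power) * df - 1), 0.05)   # Parseval on unit variance
  # a pure 5 Hz tone peaks in the right bin
  tt <- seq(0, 120, by = 1 / fs)
  tone <- sin(2 * pi * 5 * tt)
  sp_tone <- welch_psd(tone, fs)
  expect_equal(sp_tone$freqs[which.max(sp_tone$power)], 5, tolerance = df)
  # the amplitude factor k scales the density verbatim
  sp_k <- welch_psd(x, fs, scale_k = 3.5)
  expect_equal(sp_k$power, 3.5 * sp$power)
  expect_error(welch_psd(x[1:100], fs, segment_length = 4096), "two segments")
})

test_that("zero-phase Butterworth filters match their transfer functions", {
  fs <- 250
  tt <- seq(0, 600, by = 1 / fs)
  # DC passes untouched
  expect_equal(lowpass(rep(2.5, 5000), fs, 0.1), rep(2.5, 5000),
               tolerance = 1e-6)
  # 1 Hz tone attenuated >= 100x by the 0.1 Hz low-pass
  s1 <- sin(2 * pi * 1 * tt)
  expect_lt(stats::sd(lowpass(s1, fs, 0.1)) / stats::sd(s1), 0.01)
  # 0.01 Hz tone preserved within 5% (interior window avoids edges)
  s001 <- sin(2 * pi * 0.01 * tt)
  core <- seq(round(length(tt) * 0.25), round(length(tt) * 0.75))
  expect_equal(stats::sd(lowpass(s001, fs, 0.1)[core]) / stats::sd(s001[core]),
               1, tolerance = 0.05)
  expect_error(lowpass(s1, fs, cutoff = 200), "cutoff")
})

test_that("pair correlations behave on identical, independent and constant signals", {
  set.seed(2)
  fs <- 250
  base <- rnorm(fs * 300)
  x <- rbind(base, base)
  cr <- pair_correlations(x, fs, cutoff = 0.1)
  expect_equal(cr$max_r, 1, tolerance = 1e-10)
  ind <- matrix(rnorm(4 * fs * 300), 4)
  cri <- pair_correlations(ind, fs, cutoff = NULL)
  expect_lt(max(abs(cri$pair_r)), 0.1)
  expect_gte(cri$max_r, cri$mean_r)
  const <- rbind(base, base, rep(1, length(base)))
  expect_warning(pair_correlations(const, fs, cutoff = NULL), "constant")
})

test_that("auto/cross spectra collapse and separate in the limiting cases", {
  set.seed(3)
  fs <- 250
  n <- fs * 400
  a <- matrix(rnorm(n), 1)
  # second sample = copy of the first: cross curve equals auto curve
  ac_same <- auto_cross_psd(a, a, fs, segment_length = 16384, cutoff = NULL)
  expect_equal(ac_same$cross$power, ac_same$auto$power, tolerance = 1e-8)
  # independent signals: coherent cross power far below auto power
  b <- matrix(rnorm(3 * n), 3)
  a2 <- matrix(rnorm(3 * n), 3)
  ac_ind <- auto_cross_psd(a2, b, fs, segment_length = 16384, cutoff = NULL)
  expect_lt(band_power(ac_ind$cross, c(0.1, 10)) /
              band_power(ac_ind$auto, c(0.1, 10)), 0.15)
})

test_that("power-law fits are exact on synthetic laws and flat on white noise", {
  freqs <- seq(0.05, 20, by = 0.05)
  for (expo in c(-3, -2, -1.2, 0)) {
    sp <- synthetic_spectrum(freqs, 2 * freqs^expo)
    fit <- fit_powerlaw(sp, 0.1, 10)
    expect_equal(fit$exponent, expo, tolerance = 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-6)
  }
  set.seed(4)
  spw <- welch_psd(rnorm(2^17), 250)
  expect_equal(fit_powerlaw(spw, 0.1, 10)$exponent, 0, tolerance = 0.05)
  sp_bad <- synthetic_spectrum(freqs, c(-1, rep(1, length(freqs) - 1)))
  expect_error(fit_powerlaw(sp_bad, 0.04, 10), "nonpositive")
})

test_that("Lorentzian fits recover synthetic and simulated knees", {
  freqs <- exp(seq(log(0.05), log(100), length.out = 400))
  sp <- synthetic_spectrum(freqs, 3 / (1 + (freqs / 5)^2))
  fit <- fit_lorentzian(sp)
  expect_equal(fit$amplitude, 3, tolerance = 0.01)
  expect_equal(fit$knee_freq, 5, tolerance = 0.01 * 5)
  # an isolated rate unit has knee 1/(2 pi tau)
  p <- network_params(n_units = 4, sparseness = 0, tau = 0.020, seed = 6)
  tr <- simulate_rates(build_weights(p), drive = noise_spec(seed = 5),
                       duration = 400)
  spu <- welch_psd(tr$values[1, ], tr$fs)
  fitu <- fit_lorentzian(spu)
  expect_equal(fitu$knee_freq, knee_from_tau(0.020),
               tolerance = 0.1 * knee_from_tau(0.020))
  expect_error(fit_lorentzian(synthetic_spectrum(seq(1, 5, 0.1),
                                                 rep(1, 41))),
               "two frequency decades")
})

test_that("band powers and spectral ratios satisfy their identities", {
  freqs <- seq(0.01, 50, by = 0.01)
  s1 <- synthetic_spectrum(freqs, rep(2, length(freqs)))
  s10 <- synthetic_spectrum(freqs, rep(20, length(freqs)))
  expect_equal(log_power_ratio(s1, s1), 0)
  expect_equal(log_power_ratio(s10, s1), 1)
  # antisymmetry under swapping auto and cross
  expect_equal(log_power_ratio(s1, s10), -log_power_ratio(s10, s1))
  # linearity of band power in the spectrum amplitude
  expect_equal(band_power(s10, c(0.01, 0.1)), 10 * band_power(s1, c(0.01, 0.1)))
  sp_slope <- synthetic_spectrum(freqs, freqs^-1)
  expect_gt(slow_fast_ratio(sp_slope), 1)
  expect_error(band_power(s1, c(60, 80)), "no frequency bins")
})

test_that("spectrum estimates round-trip through CSV with metadata", {
  set.seed(8)
  sp <- welch_psd(rnorm(2^14), 250, segment_length = 2048, scale_k = 2)
  path <- tempfile(fileext = ".csv")
  write_spectrum(sp, path)
  sp2 <- read_spectrum(path)
  expect_equal(sp2$freqs, sp$freqs)
  expect_equal(sp2$power, sp$power)
  expect_equal(sp2$scale_k, 2)
  expect_equal(sp2$segment_length, 2048)
  unlink(c(path, paste0(path, ".json")))
})
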