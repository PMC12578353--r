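test_that("Benjamini-Hochberg adjustment equals the textbook step-up", {
  set.seed(10)
  for (i in 1:25) {
    p <- runif(20)^sample(1:3, 1)
    expect_equal(stats::p.adjust(p, method = "BH"), brute_bh(p))
  }
})

test_that("the exact signed-rank p matches full enumeration for small n", {
  set.seed(11)
  for (n in 5:8) {
    for (rep in 1:3) {
      x <- rnorm(n, mean = 0.4)
      y <- rnorm(n)
      p_r <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
      expect_equal(p_r, brute_signrank_p(x, y), tolerance = 1e-12)
    }
  }
})

test_that("effective sample size tracks residual autocorrelation", {
  freqs <- seq(0.05, 10, length.out = 2000)
  sim <- synthetic_spectrum(freqs, freqs^-1)
  # identical spectra: perfect fit, no correction
  g0 <- goodness_of_fit(sim, sim)
  expect_equal(g0$r_squared_log, 1)
  expect_equal(g0$n_eff, g0$n_bins)
  expect_equal(g0$p_value, 0)
  # iid residuals: n_eff stays close to the bin count
  set.seed(12)
  ref_iid <- synthetic_spectrum(freqs, freqs^-1 * 10^rnorm(2000, 0, 0.1))
  g_iid <- goodness_of_fit(sim, ref_iid)
  expect_lt(abs(g_iid$n_eff / g_iid$n_bins - 1), 0.2)
  # AR(1) residuals, phi = 0.8: n_eff ~ N (1 - phi) / (1 + phi)
  eps <- as.numeric(stats::arima.sim(list(ar = 0.8), 2000, sd = 0.05))
  ref_ar <- synthetic_spectrum(freqs, freqs^-1 * 10^eps)
  g_ar <- goodness_of_fit(sim, ref_ar)
  expect_lt(abs(g_ar$n_eff / (2000 * 0.2 / 1.8) - 1), 0.25)
  # residuals dominated by one slow drift leave too few effective samples
  freqs100 <- seq(0.05, 10, length.out = 100)
  sim100 <- synthetic_spectrum(freqs100, freqs100^-1)
  ref_slow <- synthetic_spectrum(freqs100, freqs100^-1 *
                                   10^seq(0, 2, length.out = 100))
  expect_error(goodness_of_fit(sim100, ref_slow), "effective sample size")
})

fake_scan <- function(g = seq(0.80, 0.99, by = 0.01),
                      log_ratio = seq(2, 0.1, length.out = length(g)),
                      max_r = seq(0.3, 0.9, length.out = length(g)),
                      mean_r = seq(0.05, 0.9, length.out = length(g))) {
  structure(list(summary = data.frame(G = g, max_r = max_r, mean_r = mean_r,
                                      log_ratio = log_ratio,
                                      exponent_ratio = NA_real_,
                                      n_ok = 5L),
                 raw = NULL, cfg = list(g_grid = g, n_realizations = 5)),
            class = "scan_result")
}

test_that("G* interpolation is exact on synthetic calibration curves", {
  sc <- fake_scan()
  # linear curve: closed-form crossing
  slope <- (0.1 - 2) / (0.99 - 0.80)
  g_expected <- 0.80 + (0.84 - 2) / slope
  cal <- calibrate_Gstar(sc, 0.84)
  expect_equal(cal$g_star, g_expected, tolerance = 1e-10)
  # target equal to a grid value lands exactly on that grid point
  target <- sc$summary$log_ratio[6]
  expect_equal(calibrate_Gstar(sc, target)$g_star, sc$summary$G[6],
               tolerance = 1e-10)
  expect_error(calibrate_Gstar(sc, 5), "outside")
})

test_that("threshold readouts pick the first qualifying grid point", {
  sc <- fake_scan(max_r = c(rep(0.3, 11), rep(0.7, 9)),
                  mean_r = c(rep(0.1, 16), rep(0.6, 4)))
  expect_equal(first_G_reaching(sc, "max_r", 0.56), 0.91)
  expect_equal(first_G_reaching(sc, "mean_r", 0.56), 0.96)
  expect_true(is.na(first_G_reaching(sc, "mean_r", 0.99)))
})

test_that("slow-fluctuation coupling grows with the control parameter", {
  cfg <- scan_config(g_grid = c(0.5, 0.8, 0.95), n_realizations = 3,
                     duration = 120, discard = 30,
                     params = network_params(n_units = 60),
                     n_corr_units = 6, seed = 42)
  sc <- suppressWarnings(correlation_scan(cfg))
  expect_equal(nrow(sc$summary), 3)
  expect_true(all(diff(sc$summary$mean_r) > 0))
  expect_true(all(sc$summary$max_r >= sc$summary$mean_r))
  # near zero coupling deep in the subcritical regime
  expect_lt(sc$summary$mean_r[1], 0.2)
})

test_that("recall contrast flips sign when condition labels swap", {
  p <- network_params(n_units = 40)
  proto <- block_protocol(block_length = 120, discard = 20,
                          conditions = list(rest = noise_spec(dc_offset = 0),
                                            recall = noise_spec(dc_offset = 12.5)))
  rc <- recall_contrast(n_realizations = 6, g = 0.9, params = p,
                        protocol = proto,
                        proxy = proxy_spec(alpha = 0.1, n_samples = 1),
                        segment_length = 8192, seed = 77)
  proto_sw <- proto
  proto_sw$conditions <- proto$conditions[c("recall", "rest")]
  rc_sw <- recall_contrast(n_realizations = 6, g = 0.9, params = p,
                           protocol = proto_sw,
                           proxy = proxy_spec(alpha = 0.1, n_samples = 1),
                           segment_length = 8192, seed = 77)
  expect_equal(rc_sw$effect, -rc$effect, tolerance = 1e-10)
  expect_equal(rc_sw$p_raw, rc$p_raw, tolerance = 1e-10)
  # adjusted p dominates raw p and the additive shift amplifies slow power
  expect_true(all(rc$p_adj >= rc$p_raw - 1e-12))
  expect_gt(mean(rc$effect), 0)
})

test_that("identical conditions yield a degenerate paired contrast", {
  p <- network_params(n_units = 30)
  proto <- block_protocol(block_length = 80, discard = 20,
                          conditions = list(rest = noise_spec(),
                                            recall = noise_spec()))
  expect_warning(
    rc <- recall_contrast(n_realizations = 5, g = 0.8, params = p,
                          protocol = proto,
                          proxy = proxy_spec(alpha = 0.2, n_samples = 1),
                          segment_length = 4096, seed = 5),
    "identical")
  expect_true(all(rc$effect == 0))
  expect_true(all(is.na(rc$p_raw)))
})

test_that("heatmap cells grow toward criticality with the expected shape", {
  hm <- size_gain_heatmap(sizes = c(40, 60), g_grid = c(0.5, 0.9), reps = 1,
                          duration = 90, discard = 20,
                          segment_length = 8192, seed = 3)
  expect_equal(dim(hm$values), c(2, 2))
  expect_true(all(hm$values[, 2] > hm$values[, 1]))
})

test_that("effective-gain dispersion shrinks with network size", {
  tab <- effective_gain_vs_size(sizes = c(30, 120), reps = 15, seed = 6)
  expect_equal(nrow(tab), 2)
  expect_gt(tab$sd[1], tab$sd[2])
  expect_gt(tab$q75[1] - tab$q25[1], tab$q75[2] - tab$q25[2])
  expect_lt(abs(tab$median[2] - 1), 0.05)
})

test_that("additive-noise sensitivity rejects degenerate level designs", {
  expect_error(additive_noise_sensitivity(levels = c(5, 10)), "include 0")
  expect_error(additive_noise_sensitivity(levels = c(0, 0)), "distinct")
})

test_that("noise-robustness runs are reproducible under a fixed seed", {
  args <- list(g = 0.9, params = network_params(n_units = 50),
               filters = list(white = NULL), connectivity = "near_critical",
               duration = 90, discard = 20, segment_length = 8192, seed = 12)
  r1 <- do.call(noise_profile_robustness, args)
  r2 <- do.call(noise_profile_robustness, args)
  expect_equal(r1$summary, r2$summary)
})
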