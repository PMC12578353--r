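test_that("control parameter and its inverse follow the printed relation", {
  # reference configuration sits at the critical point
  expect_equal(control_parameter(0.1, 0.2, 49.881), 0.99762, tolerance = 1e-6)
  expect_identical(control_parameter(0, 0.2, 49.881), 0)
  # algebraic inverse and round trips
  expect_equal(gamma_for_G(1, 0.2, 49.881), 0.1002386, tolerance = 1e-6)
  g95 <- gamma_for_G(0.95, 0.2, 49.881)
  expect_equal(control_parameter(g95, 0.2, 49.881), 0.95, tolerance = 1e-12)
  expect_identical(gamma_for_G(0, 0.2, 49.881), 0)
  expect_equal(control_parameter(gamma_for_G(0.96, 0.2, 49.881), 0.2, 49.881),
               0.96, tolerance = 1e-12)
  expect_error(control_parameter(-0.1, 0.2, 49.881), "nonnegative")
  expect_error(gamma_for_G(0.5, 0, 49.881), "positive")
})

test_that("network_params validates its invariants", {
  expect_error(network_params(n_units = 1), "n_units")
  expect_error(network_params(sparseness = 1.2), "sparseness")
  expect_error(network_params(dt = 0.005), "tau / 10")
  expect_error(network_params(conn_mean = NaN), "finite")
})

test_that("weight realizations match the sparse-normal generative law", {
  p <- network_params(seed = 101)
  W <- build_weights(p)
  # binomial concentration of the realized sparseness over N^2 entries
  expect_lt(abs(W$realized_sparseness - 0.2), 0.008)
  nz <- W$weights[W$weights != 0]
  se <- (p$conn_sd / p$n_units) / sqrt(length(nz))
  expect_lt(abs(mean(nz) - p$conn_mean / p$n_units), 4 * se)
  # reproducibility by seed
  expect_identical(W$weights, build_weights(p)$weights)
  # zero-sparseness edge case
  W0 <- build_weights(network_params(sparseness = 0, seed = 1))
  expect_true(all(W0$weights == 0))
  expect_equal(linearize(W0)$effective_gain, 0)
})

test_that("linearization matches closed forms and a brute-force oracle", {
  # 2x2 symmetric: eigenvalues a +/- b
  W2 <- matrix(c(2, 1, 1, 2), 2)
  lr <- linearize(W2, gain = 0.5, tau = 0.02)
  expect_equal(sort(Re(lr$eigenvalues)), 0.5 * c(1, 3), tolerance = 1e-12)
  expect_equal(lr$effective_gain, 1.5, tolerance = 1e-12)
  # zero matrix
  lr0 <- linearize(matrix(0, 3, 3), gain = 0.1, tau = 0.02)
  expect_equal(lr0$effective_gain, 0)
  expect_equal(lr0$predicted_timescale, 0.02)
  expect_lt(lr0$jacobian_dominant, 0)
  # random small matrices vs characteristic-polynomial roots
  set.seed(7)
  for (n in c(3, 5, 6)) {
    m <- matrix(rnorm(n * n), n)
    ev <- sort(Re(linearize(m, gain = 1, tau = 0.02)$eigenvalues))
    ev_oracle <- sort(Re(charpoly_eigen(m)))
    expect_equal(ev, ev_oracle, tolerance = 1e-8)
  }
})

test_that("linearization report internal relations hold across regimes", {
  set.seed(11)
  for (g in c(0.3, 0.8, 0.99, 1.05)) {
    p <- tiny_params(n = 80, g = g, seed = sample.int(1e6, 1))
    lr <- linearize(build_weights(p))
    expect_equal(lr$jacobian_dominant < 0, lr$effective_gain < 1)
    if (lr$effective_gain < 1)
      expect_equal(lr$predicted_timescale,
                   p$tau / (1 - lr$effective_gain), tolerance = 1e-12)
  }
  # predicted timescale diverges monotonically toward criticality
  ts <- sapply(c(0.5, 0.8, 0.9, 0.99), function(ge) 0.02 / (1 - ge))
  expect_true(all(diff(ts) > 0))
})

test_that("effective gain concentrates at G = 1 as networks grow", {
  set.seed(3)
  sds <- sapply(c(50, 100, 200, 400), function(n) {
    effs <- replicate(12, {
      p <- network_params(n_units = n, gain = gamma_for_G(1, 0.2, 49.881),
                         seed = sample.int(.Machine$integer.max, 1))
      linearize(build_weights(p))$effective_gain
    })
    stats::sd(effs)
  })
  expect_true(all(diff(sds) < 0))
  # large networks sit close to the theoretical value
  set.seed(4)
  effs240 <- replicate(12, {
    p <- network_params(gain = gamma_for_G(1, 0.2, 49.881),
                        seed = sample.int(.Machine$integer.max, 1))
    linearize(build_weights(p))$effective_gain
  })
  expect_lt(abs(mean(effs240) - 1), 0.02)
})

test_that("simulation honors trivial closed-form cases", {
  # zero drive, zero initial state: identically zero
  p <- tiny_params(n = 10, g = 0.9, seed = 2)
  W <- build_weights(p)
  tr0 <- simulate_rates(W, drive = noise_spec(mean = 0, sd = 0, seed = 1),
                        duration = 2)
  expect_true(all(tr0$values == 0))
  # disconnected units with constant drive relax to gain * I with
  # e-folding time tau
  p0 <- network_params(n_units = 5, sparseness = 0, gain = 0.1, seed = 3)
  W0 <- build_weights(p0)
  trc <- simulate_rates(W0, drive = noise_spec(mean = 30, sd = 0, seed = 1),
                        duration = 1)
  at5tau <- trc$values[1, round(5 * p0$tau * trc$fs)]
  expect_equal(at5tau, 0.1 * 30, tolerance = 0.02)
  # rates are nonnegative under noisy drive (small subcritical net)
  ps <- tiny_params(n = 10, g = 0.5, seed = 2)
  trn <- simulate_rates(build_weights(ps),
                        drive = noise_spec(mean = 0, sd = 20, seed = 5),
                        duration = 5)
  expect_true(all(trn$values >= 0))
})

test_that("uniform-mode perturbations decay at the linearized timescale", {
  set.seed(21)
  for (g in c(0.3, 0.5, 0.8)) {
    p <- tiny_params(n = 100, g = g, seed = sample.int(1e6, 1))
    W <- build_weights(p)
    g_eff <- linearize(W)$effective_gain
    tr <- simulate_rates(W, drive = noise_spec(mean = 0, sd = 0, seed = 1),
                         duration = 1.5, initial_state = rep(5, 100),
                         fs_out = 1000)
    m <- colMeans(tr$values)
    tt <- seq_along(m) / tr$fs
    # fit the exponential over a 2-decade window after a short transient
    win <- which(tt > 0.03 & m > max(m) * 1e-3 & m > 0)
    fit <- stats::lm(log(m[win]) ~ tt[win])
    tau_fit <- -1 / stats::coef(fit)[2]
    expect_equal(unname(tau_fit), p$tau / (1 - g_eff), tolerance = 0.1)
  }
})

test_that("supercritical runaway trips the overflow guard", {
  p <- network_params(n_units = 200, gain = gamma_for_G(1.1, 0.2, 49.881),
                      seed = 9)
  W <- build_weights(p)
  expect_gt(linearize(W)$effective_gain, 1)
  expect_error(
    simulate_rates(W, drive = noise_spec(mean = 20, sd = 11.5, seed = 1),
                   duration = 60),
    "supercritical runaway")
})

test_that("halving the integration step leaves band powers nearly unchanged", {
  p1 <- network_params(n_units = 40, gain = gamma_for_G(0.9, 0.2, 49.881),
                       dt = 0.001, seed = 31)
  W <- build_weights(p1)
  set.seed(55)
  n_steps <- 60 * 1000
  drv <- matrix(20 + 11.5 * rnorm(40 * n_steps), 40, n_steps)
  tr1 <- simulate_rates(W, p1, drive = drv, duration = 60)
  # same frozen-per-step noise, held over two half-steps
  p2 <- network_params(n_units = 40, gain = p1$gain, dt = 0.0005, seed = 31)
  drv2 <- drv[, rep(seq_len(n_steps), each = 2)]
  tr2 <- simulate_rates(W$weights, p2, drive = drv2, duration = 60)
  s1 <- welch_psd(colSums(tr1$values), tr1$fs, segment_length = 4096)
  s2 <- welch_psd(colSums(tr2$values), tr2$fs, segment_length = 4096)
  bp1 <- band_power(s1, c(0.1, 10))
  bp2 <- band_power(s2, c(0.1, 10))
  expect_lt(abs(bp1 / bp2 - 1), 0.05)
})

test_that("traces round-trip and burn-in bookkeeping is exact", {
  p <- tiny_params(n = 12, g = 0.8, seed = 8)
  tr <- simulate_rates(build_weights(p), drive = noise_spec(seed = 2),
                       duration = 20)
  expect_equal(ncol(tr$values), 20 * 250)
  tr2 <- discard_burnin(tr, 5)
  expect_equal(ncol(tr2$values), 15 * 250)
  expect_equal(tr2$t_start, 5)
  expect_identical(tr2$values, tr$values[, -(1:1250)])
})
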