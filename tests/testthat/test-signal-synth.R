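test_that("drive generation matches its spec: moments, offsets, shaping", {
  # degenerate noiseless case: constant I_ext + I_add stream
  d <- make_drive(noise_spec(mean = 20, sd = 0, dc_offset = 12.5, seed = 1),
                  n_units = 3, n_steps = 100)
  expect_true(all(d == 32.5))
  # law of large numbers on the sample mean
  d2 <- make_drive(noise_spec(mean = 0, sd = 1, seed = 2), 1, 1e5)
  expect_lt(abs(mean(d2)), 4 / sqrt(1e5))
  # high-pass shaping: slow band suppressed >= 10x, marginal mean kept
  spec_hp <- noise_spec(mean = 20, sd = 5,
                        filter = list(cutoff = 3, order = 4, type = "high"),
                        seed = 3)
  n_steps <- 200000
  hp <- make_drive(spec_hp, 1, n_steps, dt = 0.001)
  wh <- make_drive(noise_spec(mean = 20, sd = 5, seed = 3), 1, n_steps,
                   dt = 0.001)
  s_hp <- welch_psd(hp[1, ], 1000, segment_length = 16384)
  s_wh <- welch_psd(wh[1, ], 1000, segment_length = 16384)
  expect_lt(band_power(s_hp, c(0.1, 1)) / band_power(s_wh, c(0.1, 1)), 0.1)
  expect_lt(abs(mean(hp) - 20), 4 * 5 / sqrt(n_steps))
})

test_that("proxy summation is linear, reproducible and disjoint", {
  p <- tiny_params(n = 240, g = 0, seed = 5)
  tr <- simulate_rates(build_weights(p), drive = noise_spec(seed = 7),
                       duration = 4)
  # alpha = 1: the full column sum
  px_all <- ieeg_proxy(tr, proxy_spec(alpha = 1, n_samples = 1, seed = 1))
  expect_equal(px_all$proxies[1, ], colSums(tr$values))
  # alpha = 0.01 with N = 240: two units per sample, samples disjoint
  px <- ieeg_proxy(tr, proxy_spec(alpha = 0.01, n_samples = 2, seed = 2))
  expect_length(px$sample_ids[[1]], 2)
  expect_length(intersect(px$sample_ids[[1]], px$sample_ids[[2]]), 0)
  # reproducible by seed
  px2 <- ieeg_proxy(tr, proxy_spec(alpha = 0.01, n_samples = 2, seed = 2))
  expect_identical(px$sample_ids, px2$sample_ids)
  # identical unit traces: proxy = k x single trace
  tr_id <- tr
  tr_id$values <- matrix(rep(tr$values[1, ], each = 240), nrow = 240)
  px_id <- ieeg_proxy(tr_id, proxy_spec(alpha = 0.05, n_samples = 1, seed = 3))
  expect_equal(px_id$proxies[1, ], 12 * tr$values[1, ])
  # alpha * N < 1 is raised to a single unit, with a warning
  expect_warning(ieeg_proxy(tr, proxy_spec(alpha = 0.001, n_samples = 1,
                                           seed = 4)),
                 "raised to 1")
})

test_that("stationarity trimming removes drifting prefixes and is idempotent", {
  fs <- 10
  set.seed(6)
  # already-stationary noise: nothing removed
  x_ok <- rnorm(900 * fs)
  tr_ok <- trim_to_stationary(x_ok, fs)
  expect_equal(tr_ok$discarded, 0)
  expect_lt(tr_ok$p_value, 0.01)
  # a unit-root (random walk) prefix continuing into stationary noise:
  # trimming removes a nonzero stretch, never more than the prefix plus
  # two steps, and the remainder tests stationary. (A deterministic ramp
  # is trend-stationary and does not trip a constant-only unit-root
  # test, so the drifting prefix must itself be integrated.)
  set.seed(6)
  walk <- cumsum(rnorm(300 * fs, 0, 0.5))
  x_walk <- c(walk, walk[length(walk)] + rnorm(300 * fs))
  tr_walk <- trim_to_stationary(x_walk, fs, step = 10)
  expect_gt(tr_walk$discarded, 0)
  expect_lte(tr_walk$discarded, 320)
  expect_lt(tr_walk$p_value, 0.01)
  # idempotence
  again <- trim_to_stationary(tr_walk$signal, fs, step = 10)
  expect_equal(again$discarded, 0)
  # a random walk never stabilizes
  expect_error(trim_to_stationary(cumsum(rnorm(300 * fs)), fs, step = 50),
               "no suffix")
  # fixed-discard mode mirrors the block-protocol convention
  tr_fix <- trim_to_stationary(x_ok, fs, mode = "fixed", fixed_discard = 300)
  expect_equal(tr_fix$discarded, 300)
  expect_length(tr_fix$signal, 600 * fs)
})

test_that("block protocol pairs conditions on identical noise streams", {
  p <- tiny_params(n = 40, g = 0.9, seed = 12)
  W <- build_weights(p)
  proto <- block_protocol(block_length = 80, discard = 20,
                          conditions = list(rest = noise_spec(dc_offset = 0),
                                            recall = noise_spec(dc_offset = 12.5)))
  out <- run_block_protocol(W, p, proto, proxy_spec(alpha = 0.1, n_samples = 1),
                            noise_seed = 5, proxy_seed = 6)
  rest <- out$rest$proxy$proxies[1, ]
  recall <- out$recall$proxy$proxies[1, ]
  # the additive shift raises the baseline level
  expect_gt(mean(recall), mean(rest))
  # same weights, same noise, same offset: identical trajectories
  proto_null <- block_protocol(block_length = 80, discard = 20,
                               conditions = list(a = noise_spec(),
                                                 b = noise_spec()))
  out_null <- run_block_protocol(W, p, proto_null,
                                 proxy_spec(alpha = 0.1, n_samples = 1),
                                 noise_seed = 5, proxy_seed = 6)
  expect_identical(out_null$a$proxy$proxies, out_null$b$proxy$proxies)
  # gain-multiplier route also raises activity
  proto_gain <- block_protocol(block_length = 80, discard = 20,
                               conditions = list(rest = noise_spec(),
                                                 recall = list(gain_mult = 1.05)))
  out_gain <- run_block_protocol(W, p, proto_gain,
                                 proxy_spec(alpha = 0.1, n_samples = 1),
                                 noise_seed = 5, proxy_seed = 6)
  expect_gt(mean(out_gain$recall$proxy$proxies),
            mean(out_gain$rest$proxy$proxies))
})

test_that("weights and traces persist to text and back", {
  p <- tiny_params(n = 8, g = 0.7, seed = 14)
  W <- build_weights(p)
  wp <- tempfile(fileext = ".csv")
  write_weights(W, wp)
  W2 <- read_weights(wp)
  expect_equal(W2$weights, W$weights, tolerance = 1e-12)
  expect_equal(W2$params$gain, p$gain)
  expect_equal(W2$realized_sparseness, W$realized_sparseness)
  tr <- simulate_rates(W, drive = noise_spec(seed = 3), duration = 2)
  tp <- tempfile(fileext = ".csv")
  write_traces(tr, tp)
  tr2 <- read_traces(tp)
  expect_equal(tr2$values, tr$values, tolerance = 1e-12)
  expect_equal(tr2$fs, tr$fs)
  unlink(c(wp, paste0(wp, ".json"), tp, paste0(tp, ".json")))
})

test_that("configuration round-trips through YAML", {
  path <- tempfile(fileext = ".yaml")
  net <- network_params(n_units = 120, gain = 0.095, seed = 4)
  noi <- noise_spec(mean = 18, sd = 10, dc_offset = 2,
                    filter = list(cutoff = 3, order = 4, type = "high"))
  prx <- proxy_spec(alpha = 0.02, n_samples = 2, seed = 9)
  write_config(path, net, noi, prx)
  cfg <- read_config(path)
  expect_equal(cfg$network$n_units, 120L)
  expect_equal(cfg$network$gain, 0.095)
  expect_equal(cfg$noise$filter$cutoff, 3)
  expect_equal(cfg$proxy$alpha, 0.02)
  expect_equal(cfg$bands$slow, c(0.01, 0.1))
  unlink(path)
})
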