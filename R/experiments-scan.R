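#' Configuration of a control-parameter scan
#'
#' Describes a sweep of the control parameter G (varied through the gain
#' `gamma` with connectivity statistics fixed) with several network
#' realizations per grid point, the quantities measured per realization
#' being the pairwise correlations of slow fluctuations and the
#' auto/cross spectral ratio.
#'
#' @param g_grid Control-parameter grid inside `[0, 1)`; default
#'   0.80 to 0.99 in steps of 0.01.
#' @param n_realizations Realizations (fresh weights and noise) per G.
#' @param duration Analyzed duration per realization after discard,
#'   seconds.
#' @param discard Initial stabilization period, seconds.
#' @param params Base [network_params()]; its gain is overridden per G.
#' @param noise Base [noise_spec()].
#' @param proxy [proxy_spec()] used for the two disjoint samples feeding
#'   auto/cross spectra.
#' @param n_corr_units Number of randomly sampled units over which pair
#'   correlations are computed (all distinct pairs among them); the
#'   default of 16 mirrors the scale of a multi-contact electrode
#'   ensemble. The maximum-correlation statistic grows with the number
#'   of pairs, so it is tied to this ensemble size.
#' @param corr_cutoff Low-pass cutoff for the correlation analysis, Hz.
#' @param ratio_band Band for the auto/cross mean-power log ratio, Hz.
#' @param segment_length Welch segment length (samples) for the
#'   ultra-slow spectra.
#' @param seed Master seed; all realization seeds derive from it.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(g_grid = seq(0.80, 0.99, by = 0.01),
                        n_realizations = 5, duration = 400, discard = 100,
                        params = network_params(), noise = noise_spec(),
                        proxy = proxy_spec(alpha = 0.01, n_samples = 2),
                        n_corr_units = 6, corr_cutoff = 0.1,
                        ratio_band = c(0.01, 0.1), segment_length = 32768,
                        seed = 1) {
  if (any(g_grid < 0 | g_grid >= 1))
    stop("scan_config: g_grid must lie in [0, 1)")
  if (n_realizations < 1) stop("scan_config: n_realizations must be >= 1")
  structure(list(g_grid = g_grid, n_realizations = n_realizations,
                 duration = duration, discard = discard, params = params,
                 noise = noise, proxy = proxy,
                 n_corr_units = n_corr_units, corr_cutoff = corr_cutoff,
                 ratio_band = ratio_band, segment_length = segment_length,
                 seed = seed),
            class = "scan_config")
}

#' Scan correlations and spectral ratios across the control parameter
#'
#' For each G on the grid and each realization: build a fresh weight
#' matrix with the gain set by [gamma_for_G()], simulate under white-noise
#' drive, discard the stabilization period, then measure (i) the maximum
#' and mean pairwise Pearson correlation of < `corr_cutoff` Hz low-passed
#' activity over a random subset of units, and (ii) the log10 ratio of
#' mean auto- to mean cross-spectral power in `ratio_band`, with
#' auto-spectra from the first of two disjoint unit samples and
#' cross-spectra across the samples. A power-law exponent ratio
#' (cross/auto in `ratio_band`) is recorded as the alternative calibration
#' statistic. Realizations that run away supercritically are dropped with
#' a warning.
#'
#' @param cfg A [scan_config()].
#' @param progress Print one line per grid point.
#' @return An object of class `scan_result`: `summary` (one row per G
#'   with realization means), `raw` (one row per realization), `cfg`.
#' @export
correlation_scan <- function(cfg = scan_config(), progress = FALSE) {
  stopifnot(inherits(cfg, "scan_config"))
  set.seed(cfg$seed)
  n_g <- length(cfg$g_grid)
  n_r <- cfg$n_realizations
  seeds <- matrix(sample.int(.Machine$integer.max, 3 * n_g * n_r),
                  ncol = 3)
  rows <- vector("list", n_g * n_r)
  idx <- 0L
  for (gi in seq_len(n_g)) {
    g <- cfg$g_grid[gi]
    for (ri in seq_len(n_r)) {
      idx <- idx + 1L
      rows[[idx]] <- scan_one_realization(cfg, g, seeds[idx, ])
    }
    if (progress)
      message(sprintf("G = %.2f done (%d/%d)", g, gi, n_g))
  }
  raw <- do.call(rbind, rows)
  # per-statistic means with NA realizations excluded per statistic, so a
  # failed exponent fit does not drop the realization's correlations
  summary <- stats::aggregate(
    raw[, c("max_r", "mean_r", "log_ratio", "exponent_ratio")],
    by = list(G = raw$G), FUN = function(v) mean(v, na.rm = TRUE))
  summary$n_ok <- stats::aggregate(raw$ok_flag, by = list(G = raw$G),
                                   FUN = sum)$x
  structure(list(summary = summary[order(summary$G), ], raw = raw,
                 cfg = cfg),
            class = "scan_result")
}

scan_one_realization <- function(cfg, g, seed3) {
  p <- cfg$params
  pg <- network_params(p$n_units, p$sparseness, p$conn_mean, p$conn_sd,
                       gain = gamma_for_G(g, p$sparseness, p$conn_mean),
                       tau = p$tau, dt = p$dt, seed = seed3[1])
  W <- build_weights(pg)
  noise <- cfg$noise
  noise$seed <- seed3[2]
  tr <- tryCatch(
    simulate_rates(W, drive = noise, duration = cfg$duration + cfg$discard),
    error = function(e) {
      warning(sprintf("realization at G = %.3f dropped: %s", g,
                      conditionMessage(e)))
      NULL
    })
  if (is.null(tr)) {
    return(data.frame(G = g, max_r = NA_real_, mean_r = NA_real_,
                      log_ratio = NA_real_, exponent_ratio = NA_real_,
                      g_eff = NA_real_, ok_flag = 0L, seed = seed3[1]))
  }
  tr <- discard_burnin(tr, cfg$discard)
  set.seed(seed3[3])
  corr_units <- sample.int(p$n_units, min(cfg$n_corr_units, p$n_units))
  cr <- pair_correlations(tr$values[corr_units, , drop = FALSE], tr$fs,
                          cutoff = cfg$corr_cutoff)
  prx <- cfg$proxy
  prx$seed <- seed3[3]
  px <- ieeg_proxy(tr, prx)
  ac <- auto_cross_psd(px$unit_traces[[1]], px$unit_traces[[2]], tr$fs,
                       segment_length = cfg$segment_length)
  lr <- log_power_ratio(ac$auto, ac$cross, cfg$ratio_band)
  er <- tryCatch({
    ea <- fit_powerlaw(ac$auto, cfg$ratio_band[1], cfg$ratio_band[2])$exponent
    ec <- fit_powerlaw(ac$cross, cfg$ratio_band[1], cfg$ratio_band[2])$exponent
    ec / ea
  }, error = function(e) NA_real_)
  data.frame(G = g, max_r = cr$max_r, mean_r = cr$mean_r, log_ratio = lr,
             exponent_ratio = er, g_eff = NA_real_, ok_flag = 1L,
             seed = seed3[1])
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("Control-parameter scan: %d grid points x %d realizations\n",
              length(x$cfg$g_grid), x$cfg$n_realizations))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Smallest scanned G whose mean statistic reaches a threshold
#'
#' The bound-style readout of a scan: the first grid value of the control
#' parameter at which the realization-mean of `statistic` reaches
#' `threshold` (no interpolation).
#'
#' @param scan A `scan_result`.
#' @param statistic `"max_r"` or `"mean_r"`.
#' @param threshold Reference correlation level (default 0.56, the
#'   empirical inter-channel level).
#' @return The grid G value, or `NA` if never reached.
#' @export
first_G_reaching <- function(scan, statistic = c("max_r", "mean_r"),
                             threshold = 0.56) {
  stopifnot(inherits(scan, "scan_result"))
  statistic <- match.arg(statistic)
  s <- scan$summary
  hit <- which(s[[statistic]] >= threshold)
  if (!length(hit)) return(NA_real_)
  s$G[min(hit)]
}

#' Calibrate the operating point G* from the auto/cross ratio
#'
#' Finds the control-parameter value at which the scanned auto/cross
#' low-frequency statistic equals its empirical reference value, by
#' linear interpolation between the bracketing grid points. When the
#' curve crosses the target more than once (estimation noise), the
#' crossing closest to criticality is used. Both calibration statistics
#' are available: the mean-power log ratio (primary; the empirical
#' reference is 0.84) and the power-law exponent ratio.
#'
#' @param scan A `scan_result`.
#' @param empirical_log_ratio Target value of the statistic.
#' @param statistic `"log_ratio"` (default) or `"exponent_ratio"`.
#' @return An object of class `gstar_calibration`: `g_star`, `statistic`,
#'   `target`, `bracket` (the bracketing grid points) and
#'   `bracket_values` (the statistic at those points).
#' @export
calibrate_Gstar <- function(scan, empirical_log_ratio = 0.84,
                            statistic = c("log_ratio", "exponent_ratio")) {
  stopifnot(inherits(scan, "scan_result"))
  statistic <- match.arg(statistic)
  s <- scan$summary
  curve <- s[[statistic]]
  g <- s$G
  keep <- is.finite(curve)
  curve <- curve[keep]; g <- g[keep]
  if (length(g) < 2) stop("calibrate_Gstar: too few finite grid points")
  d <- curve - empirical_log_ratio
  cross <- which(d[-length(d)] * d[-1] <= 0)
  if (!length(cross)) {
    stop(sprintf(
      "calibrate_Gstar: target %.3f outside the scanned curve range [%.3f, %.3f]",
      empirical_log_ratio, min(curve), max(curve)))
  }
  i <- max(cross)  # crossing closest to criticality
  g_star <- g[i] + (g[i + 1] - g[i]) *
    (empirical_log_ratio - curve[i]) / (curve[i + 1] - curve[i])
  structure(list(g_star = g_star, statistic = statistic,
                 target = empirical_log_ratio,
                 bracket = c(g[i], g[i + 1]),
                 bracket_values = c(curve[i], curve[i + 1])),
            class = "gstar_calibration")
}

#' @export
print.gstar_calibration <- function(x, ...) {
  cat(sprintf("G* calibration (%s = %.3f): G* = %.4f (bracket %.2f-%.2f)\n",
              x$statistic, x$target, x$g_star, x$bracket[1], x$bracket[2]))
  invisible(x)
}

#' Locate the stability boundary by eigen-decomposition
#'
#' Builds fresh weight-matrix realizations for each control-parameter
#' value on a grid spanning the critical point, computes the largest real
#' part of the eigenvalues of `gamma * W` (the effective gain), and
#' reports the G at which the realization-mean effective gain crosses 1
#' — the point where the dominant Jacobian eigenvalue `(G_eff - 1)/tau`
#' changes sign.
#'
#' @param g_grid Grid of theoretical G values (default 0.9 to 1.1 by
#'   0.01).
#' @param n_seeds Realizations per grid point (default 50).
#' @param params Base [network_params()].
#' @param seed Master seed.
#' @return List with `g_grid`, `mean_effective_gain`, `boundary`
#'   (interpolated crossing of 1), and `sd_effective_gain`.
#' @export
stability_boundary_scan <- function(g_grid = seq(0.9, 1.1, by = 0.01),
                                    n_seeds = 50,
                                    params = network_params(), seed = 1) {
  set.seed(seed)
  p <- params
  mean_eff <- sd_eff <- numeric(length(g_grid))
  for (gi in seq_along(g_grid)) {
    gamma <- gamma_for_G(g_grid[gi], p$sparseness, p$conn_mean)
    effs <- replicate(n_seeds, {
      pg <- network_params(p$n_units, p$sparseness, p$conn_mean, p$conn_sd,
                           gain = max(gamma, 1e-12), tau = p$tau, dt = p$dt,
                           seed = sample.int(.Machine$integer.max, 1))
      linearize(build_weights(pg), gain = gamma, tau = p$tau)$effective_gain
    })
    mean_eff[gi] <- mean(effs)
    sd_eff[gi] <- stats::sd(effs)
  }
  d <- mean_eff - 1
  cross <- which(d[-length(d)] * d[-1] <= 0)
  boundary <- if (length(cross)) {
    i <- cross[1]
    g_grid[i] + (g_grid[i + 1] - g_grid[i]) * (1 - mean_eff[i]) /
      (mean_eff[i + 1] - mean_eff[i])
  } else NA_real_
  list(g_grid = g_grid, mean_effective_gain = mean_eff,
       sd_effective_gain = sd_eff, boundary = boundary)
}
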