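#' Run a multi-condition block protocol on one network realization
#'
#' Simulates each condition of a [block_protocol()] on the same weight
#' matrix with the same noise seed, so conditions differ only by the
#' manipulated variable: an additive current shift (`I_add` in the
#' condition's [noise_spec()]) or a gain multiplier
#' (`list(gain_mult = )`, which inherits the protocol's first noise
#' spec). The stabilization period is discarded (fixed mode) and the
#' proxy signals are returned per condition, with the same unit sample
#' across conditions.
#'
#' @param W A `weight_matrix`.
#' @param params [network_params()]; defaults to those stored in `W`.
#' @param protocol A [block_protocol()].
#' @param proxy A [proxy_spec()].
#' @param noise_seed Seed shared by every condition's noise stream.
#' @param proxy_seed Seed of the unit sample.
#' @return Named list (one element per condition) of lists with `proxy`
#'   (a `proxy_signals`), `label`, and `discarded` seconds.
#' @export
run_block_protocol <- function(W, params = NULL, protocol = block_protocol(),
                               proxy = proxy_spec(), noise_seed = 1,
                               proxy_seed = 1) {
  stopifnot(inherits(protocol, "block_protocol"))
  if (is.null(params)) params <- W$params
  base_noise <- NULL
  for (cond in protocol$conditions)
    if (inherits(cond, "noise_spec")) { base_noise <- cond; break }
  if (is.null(base_noise)) base_noise <- noise_spec()
  out <- list()
  for (label in names(protocol$conditions)) {
    cond <- protocol$conditions[[label]]
    p_run <- params
    if (inherits(cond, "noise_spec")) {
      drv <- cond
    } else if (is.list(cond) && !is.null(cond$gain_mult)) {
      drv <- base_noise
      p_run <- network_params(params$n_units, params$sparseness,
                              params$conn_mean, params$conn_sd,
                              gain = params$gain * cond$gain_mult,
                              tau = params$tau, dt = params$dt,
                              seed = params$seed)
    } else {
      stop("run_block_protocol: condition '", label,
           "' must be a noise_spec or list(gain_mult = )")
    }
    drv$seed <- noise_seed
    tr <- simulate_rates(W, params = p_run, drive = drv,
                         duration = protocol$block_length)
    tr <- discard_burnin(tr, protocol$discard)
    prx <- proxy
    prx$seed <- proxy_seed
    out[[label]] <- list(proxy = ieeg_proxy(tr, prx), label = label,
                         discarded = protocol$discard)
  }
  out
}

#' Paired rest-versus-recall spectral contrast
#'
#' The recall experiment: over `n_realizations` network realizations at a
#' near-critical operating point, simulate a rest block and a recall
#' block as a paired design (same weights, same noise seed, same proxy
#' sample within a realization; the recall condition adds a constant
#' current `I_add` to the drive, or multiplies the gain). Per frequency
#' bin below `freq_max`, a two-sided Wilcoxon signed-rank test compares
#' recall against rest power across realizations; p-values are
#' Benjamini-Hochberg adjusted over those bins.
#'
#' @param n_realizations Number of paired realizations (>= 5 for the
#'   test to be defined).
#' @param g Control parameter of the operating point (default 0.95, the
#'   calibrated resting-state value).
#' @param params Base [network_params()]; the gain is set from `g`.
#' @param protocol A [block_protocol()] with exactly two conditions; the
#'   first is the reference ("rest"), the second the contrast
#'   ("recall"). The default is rest versus a 12.5 pA additive shift
#'   with 1800 s blocks and a 600 s discard.
#' @param proxy A [proxy_spec()]; the first sample's summed signal is
#'   analyzed.
#' @param freq_max Upper edge of the tested band, Hz (default 0.2).
#' @param segment_length Welch segment length for the ultra-slow spectra.
#' @param seed Master seed.
#' @return An object of class `recall_contrast`: `freqs` (tested bins),
#'   `p_raw`, `p_adj`, `statistic` (signed-rank V per bin), `effect`
#'   (mean log10 power difference recall - rest), full-grid `mean_rest`,
#'   `mean_recall`, `sd_rest`, `sd_recall`, `all_freqs`, `band`,
#'   `n_realizations`, `conditions`.
#' @export
recall_contrast <- function(n_realizations = 8, g = 0.95,
                            params = network_params(),
                            protocol = block_protocol(),
                            proxy = proxy_spec(alpha = 0.01, n_samples = 1),
                            freq_max = 0.2, segment_length = 32768,
                            seed = 1) {
  if (length(protocol$conditions) != 2)
    stop("recall_contrast: protocol must have exactly two conditions")
  if (n_realizations < 5)
    warning("recall_contrast: fewer than 5 realizations; the signed-rank test is weak or undefined")
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max, 3 * n_realizations),
                  ncol = 3)
  p <- params
  pg <- network_params(p$n_units, p$sparseness, p$conn_mean, p$conn_sd,
                       gain = gamma_for_G(g, p$sparseness, p$conn_mean),
                       tau = p$tau, dt = p$dt)
  labels <- names(protocol$conditions)
  spectra <- list()
  for (ri in seq_len(n_realizations)) {
    pg$seed <- seeds[ri, 1]
    W <- build_weights(pg)
    blocks <- run_block_protocol(W, pg, protocol, proxy,
                                 noise_seed = seeds[ri, 2],
                                 proxy_seed = seeds[ri, 3])
    for (label in labels) {
      sp <- welch_psd(blocks[[label]]$proxy$proxies[1, ],
                      blocks[[label]]$proxy$fs,
                      segment_length = segment_length)
      spectra[[label]] <- rbind(spectra[[label]], sp$power)
    }
  }
  freqs <- welch_psd(blocks[[labels[1]]]$proxy$proxies[1, ],
                     blocks[[labels[1]]]$proxy$fs,
                     segment_length = segment_length)$freqs
  rest <- spectra[[labels[1]]]
  recall <- spectra[[labels[2]]]
  test_idx <- which(freqs < freq_max)
  p_raw <- stat <- numeric(length(test_idx))
  for (k in seq_along(test_idx)) {
    j <- test_idx[k]
    d <- recall[, j] - rest[, j]
    if (sum(d != 0) < 5) {
      # zero differences are excluded by the signed-rank convention;
      # fewer than 5 informative pairs leaves the test undefined
      warning("recall_contrast: fewer than 5 nonzero paired differences at ",
              sprintf("%.4f", freqs[j]), " Hz (identical conditions?); ",
              "test undefined")
      p_raw[k] <- NA_real_
      stat[k] <- NA_real_
      next
    }
    wt <- stats::wilcox.test(recall[, j], rest[, j], paired = TRUE,
                             alternative = "two.sided", exact = TRUE)
    p_raw[k] <- wt$p.value
    stat[k] <- unname(wt$statistic)
  }
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  structure(list(freqs = freqs[test_idx], p_raw = p_raw, p_adj = p_adj,
                 statistic = stat,
                 effect = colMeans(log10(recall[, test_idx, drop = FALSE])) -
                   colMeans(log10(rest[, test_idx, drop = FALSE])),
                 mean_rest = colMeans(rest), mean_recall = colMeans(recall),
                 sd_rest = apply(rest, 2, stats::sd),
                 sd_recall = apply(recall, 2, stats::sd),
                 all_freqs = freqs, band = c(0, freq_max),
                 n_realizations = n_realizations, conditions = labels,
                 g = g),
            class = "recall_contrast")
}

#' @export
print.recall_contrast <- function(x, ...) {
  cat(sprintf("Rest-vs-recall contrast at G = %.3f (%d paired realizations)\n",
              x$g, x$n_realizations))
  cat(sprintf("  %d bins < %.2f Hz: %d significant at BH-FDR 0.05 (max adj p = %.3g)\n",
              length(x$freqs), x$band[2], sum(x$p_adj < 0.05), max(x$p_adj)))
  cat(sprintf("  mean low-band log10 power effect (%s - %s): %+.3f\n",
              x$conditions[2], x$conditions[1], mean(x$effect)))
  invisible(x)
}
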