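#' Autocorrelation-corrected goodness of fit between spectra
#'
#' Quantifies how closely a simulated spectrum reproduces a reference
#' spectrum over `band`: the coefficient of determination in log-power
#' space, `R^2 = corr^2(log10 S_sim, log10 S_ref)`. Because neighboring
#' Welch bins are correlated (segmentation and tapering leak power), the
#' nominal number of bins N overstates the information content; the
#' significance test therefore uses an effective sample size
#' \deqn{N_{eff} = \frac{N}{1 + 2\sum_{k=1}^{K}\rho_k}}
#' where `rho_k` are lag-k autocorrelations of the log-residuals,
#' accumulated until the first `|rho_k| < 0.1`. A two-tailed t-test of
#' the log-log correlation is evaluated with `N_eff` in place of N.
#'
#' The simulated spectrum is interpolated onto the reference grid
#' (log-log linear interpolation) within the band.
#'
#' @param sim_spectrum,ref_spectrum `spectrum_estimate` objects.
#' @param band `c(lo, hi)` in Hz (default 0.05-10, the fitted range).
#' @return An object of class `gof_report`: `r_squared_log`, `rho`
#'   (residual autocorrelations used), `n_bins`, `n_eff`, `t_stat`,
#'   `p_value`, `band`.
#' @export
goodness_of_fit <- function(sim_spectrum, ref_spectrum,
                            band = c(0.05, 10)) {
  stopifnot(inherits(sim_spectrum, "spectrum_estimate"),
            inherits(ref_spectrum, "spectrum_estimate"))
  lo <- max(band[1], min(sim_spectrum$freqs), min(ref_spectrum$freqs))
  hi <- min(band[2], max(sim_spectrum$freqs), max(ref_spectrum$freqs))
  if (lo >= hi) stop("goodness_of_fit: spectra do not overlap in band")
  idx <- which(ref_spectrum$freqs >= lo & ref_spectrum$freqs <= hi)
  if (length(idx) < 5) stop("goodness_of_fit: fewer than 5 reference bins in band")
  f <- ref_spectrum$freqs[idx]
  ref <- log10(ref_spectrum$power[idx])
  sim <- stats::approx(log10(sim_spectrum$freqs),
                       log10(sim_spectrum$power), xout = log10(f))$y
  n <- length(f)
  eps <- ref - sim
  r <- stats::cor(ref, sim)
  r2 <- r^2
  if (stats::sd(eps) < .Machine$double.eps^0.5 * max(1, mean(abs(ref)))) {
    # exact match: residuals carry no autocorrelation structure
    rho <- numeric(0)
    n_eff <- n
  } else {
    ac <- stats::acf(eps, lag.max = n - 2, plot = FALSE)$acf[-1]
    K <- which(abs(ac) < 0.1)
    K <- if (length(K)) K[1] - 1 else length(ac)
    rho <- if (K >= 1) ac[seq_len(K)] else numeric(0)
    n_eff <- n / (1 + 2 * sum(rho))
    n_eff <- min(max(n_eff, 1), n)
  }
  if (n_eff < 3)
    stop(sprintf("goodness_of_fit: effective sample size %.2f < 3; residuals too correlated for inference",
                 n_eff))
  t_stat <- if (r2 >= 1) Inf else r * sqrt((n_eff - 2) / (1 - r2))
  p_value <- if (is.infinite(t_stat)) 0 else
    2 * stats::pt(-abs(t_stat), df = n_eff - 2)
  structure(list(r_squared_log = r2, rho = rho, n_bins = n, n_eff = n_eff,
                 t_stat = t_stat, p_value = p_value, band = c(lo, hi)),
            class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  cat(sprintf("Goodness of fit over [%g, %g] Hz: log-domain R^2 = %.3f\n",
              x$band[1], x$band[2], x$r_squared_log))
  cat(sprintf("  N = %d bins, N_eff = %.1f, t = %.2f, p = %.3g\n",
              x$n_bins, x$n_eff, x$t_stat, x$p_value))
  invisible(x)
}
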