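#' Predicted Lorentzian knee frequency of a first-order unit
#'
#' An isolated rate unit driven by white noise is a first-order low-pass
#' with time constant `tau`; its power spectrum is a Lorentzian whose
#' knee (transition from flat plateau to `1/f^2` decay) sits at
#' `1 / (2 * pi * tau)`.
#'
#' @param tau Time constant, seconds.
#' @return Knee frequency in Hz.
#' @export
knee_from_tau <- function(tau) {
  if (any(tau <= 0)) stop("knee_from_tau: tau must be positive")
  1 / (2 * pi * tau)
}

#' Power-law fit of a spectrum segment
#'
#' Least-squares line in log10-log10 space over the bins inside
#' `[f_lo, f_hi]`; the slope is the power-law exponent.
#'
#' @param spectrum A `spectrum_estimate`.
#' @param f_lo,f_hi Band edges in Hz (default 0.1 and 10, the mid-range
#'   regression band).
#' @return An object of class `powerlaw_fit`: `exponent`, `intercept`,
#'   `band`, `r_squared`, `n_bins`.
#' @export
fit_powerlaw <- function(spectrum, f_lo = 0.1, f_hi = 10) {
  stopifnot(inherits(spectrum, "spectrum_estimate"))
  idx <- band_bins(spectrum$freqs, c(f_lo, f_hi))
  if (length(idx) < 5) stop("fit_powerlaw: fewer than 5 bins in band")
  p <- spectrum$power[idx]
  if (any(p <= 0)) stop("fit_powerlaw: nonpositive power in band")
  lx <- log10(spectrum$freqs[idx])
  ly <- log10(p)
  fit <- stats::lm(ly ~ lx)
  rss <- sum(stats::residuals(fit)^2)
  r2 <- if (rss < 1e-20 * length(ly)) 1 else summary(fit)$r.squared
  structure(list(exponent = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 band = c(f_lo, f_hi),
                 r_squared = r2,
                 n_bins = length(idx)),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("Power-law fit over [%g, %g] Hz: exponent = %.3f (R^2 = %.3f, %d bins)\n",
              x$band[1], x$band[2], x$exponent, x$r_squared, x$n_bins))
  invisible(x)
}

#' Lorentzian fit of a spectrum
#'
#' Nonlinear least-squares fit of `S(f) = A / (1 + (f / f_knee)^2)` in
#' log10 space (so the flat plateau and the `1/f^2` tail carry comparable
#' weight). Starting values: plateau level from the lowest decade, knee
#' at the half-power crossing.
#'
#' @param spectrum A `spectrum_estimate` spanning at least two decades.
#' @param f_range Optional `c(lo, hi)` restriction in Hz; by default the
#'   fit stays below `0.4 * fs`, the passband of the decimation
#'   anti-alias filter used when traces are stored.
#' @return An object of class `lorentzian_fit`: `amplitude`, `knee_freq`,
#'   `residual_norm`, `n_bins`.
#' @export
fit_lorentzian <- function(spectrum, f_range = NULL) {
  stopifnot(inherits(spectrum, "spectrum_estimate"))
  f <- spectrum$freqs
  p <- spectrum$power
  if (is.null(f_range) && is.finite(spectrum$fs))
    f_range <- c(min(f), 0.4 * spectrum$fs)
  if (!is.null(f_range)) {
    idx <- band_bins(f, f_range)
    f <- f[idx]; p <- p[idx]
  }
  keep <- p > 0 & f > 0
  f <- f[keep]; p <- p[keep]
  if (diff(log10(range(f))) < 2)
    stop("fit_lorentzian: spectrum must span at least two frequency decades")
  a0 <- stats::median(p[f <= min(f) * 10])
  k0 <- f[which.min(abs(p - a0 / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(log10(p) ~ log10(A / (1 + (f / fk)^2)),
                      start = list(A = a0, fk = k0),
                      lower = c(A = .Machine$double.xmin, fk = min(f) / 10),
                      data = data.frame(f = f, p = p),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop(sprintf("fit_lorentzian: fit did not converge (%s); start A = %.3g, fk = %.3g",
                   conditionMessage(e), a0, k0)))
  cf <- stats::coef(fit)
  structure(list(amplitude = unname(cf["A"]), knee_freq = unname(cf["fk"]),
                 residual_norm = sqrt(sum(stats::residuals(fit)^2)),
                 n_bins = length(f)),
            class = "lorentzian_fit")
}

#' @export
print.lorentzian_fit <- function(x, ...) {
  cat(sprintf("Lorentzian fit: A = %.4g, knee = %.4g Hz (log-residual norm %.3g, %d bins)\n",
              x$amplitude, x$knee_freq, x$residual_norm, x$n_bins))
  invisible(x)
}
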