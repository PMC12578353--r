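#' Augmented Dickey-Fuller test for stationarity
#'
#' Regression-based unit-root test, constant-only variant:
#' \deqn{\Delta y_t = \alpha + \rho\, y_{t-1} + \sum_{i=1}^{L} \phi_i
#' \Delta y_{t-i} + \epsilon_t}
#' The test statistic is the t-ratio of \eqn{\rho}; large negative values
#' reject the unit-root null, i.e. support stationarity. Lag order is
#' chosen by AIC up to the Schwert rule-of-thumb maximum
#' `trunc(12 * (n/100)^0.25)`. The p-value is interpolated (log-linearly)
#' from the asymptotic quantiles of the Dickey-Fuller tau distribution
#' for the constant-only case and is clamped to `[0.001, 0.999]`; for the
#' trimming decision only the position relative to the 1% quantile
#' matters.
#'
#' @param x Numeric vector.
#' @param max_lag Maximum augmentation lag; default Schwert rule.
#' @return List with `statistic`, `p_value`, `lag` (selected order) and
#'   `n` (effective regression length).
#' @export
adf_test <- function(x, max_lag = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 20) stop("adf_test: series too short")
  if (is.null(max_lag)) max_lag <- trunc(12 * (n / 100)^0.25)
  max_lag <- min(max_lag, n %/% 3)
  dy <- diff(x)
  best <- NULL
  # single design at max_lag so AIC comparisons share a sample
  t_all <- seq(max_lag + 1, n - 1)
  y_lag <- x[t_all]
  dy_t <- dy[t_all]
  lagmat <- if (max_lag > 0)
    sapply(seq_len(max_lag), function(i) dy[t_all - i]) else NULL
  m <- length(t_all)
  for (L in 0:max_lag) {
    X <- cbind(1, y_lag, if (L > 0) lagmat[, seq_len(L), drop = FALSE])
    fit <- stats::lm.fit(X, dy_t)
    rss <- sum(fit$residuals^2)
    aic <- m * log(rss / m) + 2 * (L + 2)
    if (is.null(best) || aic < best$aic) {
      sigma2 <- rss / (m - ncol(X))
      xtx_inv <- chol2inv(chol(crossprod(X)))
      tstat <- fit$coefficients[2] / sqrt(sigma2 * xtx_inv[2, 2])
      best <- list(aic = aic, lag = L, statistic = unname(tstat))
    }
  }
  list(statistic = best$statistic,
       p_value = df_tau_pvalue(best$statistic),
       lag = best$lag, n = m)
}

# Asymptotic quantiles of the Dickey-Fuller tau distribution, constant
# case (Fuller 1976 / MacKinnon 2010 asymptotic values); interpolation is
# linear in the statistic against log(p).
df_tau_pvalue <- function(stat) {
  p <- c(0.01, 0.025, 0.05, 0.10, 0.50, 0.90, 0.95, 0.975, 0.99)
  q <- c(-3.43, -3.12, -2.86, -2.57, -1.57, -0.44, -0.07, 0.23, 0.60)
  if (stat <= q[1]) return(0.001)
  if (stat >= q[length(q)]) return(0.999)
  exp(stats::approx(q, log(p), xout = stat)$y)
}

#' Trim a signal to its stationary suffix
#'
#' Iteratively removes prefixes in increments of `step` seconds until the
#' augmented Dickey-Fuller test rejects non-stationarity on the remainder
#' at `p < p_threshold` (adaptive mode), or removes a fixed stabilization
#' period (fixed mode, mirroring the 600 s discard used in the block
#' protocol). The test runs on a copy decimated to ~10 Hz: the drifts the
#' trimming targets are slow, and decimation keeps the regression cheap
#' on quarter-hour signals.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate, Hz.
#' @param p_threshold ADF rejection level (default 0.01).
#' @param step Trimming increment, seconds (default 10).
#' @param mode `"adaptive"` (ADF-driven) or `"fixed"`.
#' @param fixed_discard Seconds removed in fixed mode (default 600).
#' @return List with `signal` (trimmed vector), `discarded` (seconds
#'   removed) and `p_value` of the final test (adaptive mode).
#' @export
trim_to_stationary <- function(x, fs, p_threshold = 0.01, step = 10,
                               mode = c("adaptive", "fixed"),
                               fixed_discard = 600) {
  mode <- match.arg(mode)
  x <- as.numeric(x)
  n <- length(x)
  step_n <- round(step * fs)
  if (n <= 2 * step_n) stop("trim_to_stationary: signal shorter than 2 steps")
  if (mode == "fixed") {
    n_drop <- round(fixed_discard * fs)
    if (n_drop >= n) stop("trim_to_stationary: fixed discard longer than signal")
    return(list(signal = x[(n_drop + 1):n], discarded = n_drop / fs,
                p_value = NA_real_))
  }
  dec <- max(1L, as.integer(round(fs / 10)))
  offset <- 0L
  repeat {
    seg <- x[(offset + 1):n]
    if (length(seg) <= 2 * step_n || length(seg) < 20 * dec)
      stop("trim_to_stationary: no suffix of the signal tests stationary at p < ",
           p_threshold)
    tst <- adf_test(seg[seq(1, length(seg), by = dec)])
    if (tst$p_value < p_threshold) {
      return(list(signal = seg, discarded = offset / fs,
                  p_value = tst$p_value))
    }
    offset <- offset + step_n
  }
}
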