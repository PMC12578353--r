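#' Pairwise correlations of slow activity fluctuations
#'
#' Low-pass filters each signal (Butterworth, default < 0.1 Hz, zero
#' phase) and computes Pearson correlations over all distinct pairs at
#' zero lag; an optional mode takes, per pair, the maximum correlation
#' over lags up to `max_lag` seconds. Constant signals yield undefined
#' correlations and are excluded with a warning.
#'
#' @param x Matrix with one signal per row (>= 2 rows).
#' @param fs Sampling rate, Hz.
#' @param cutoff Low-pass cutoff, Hz; `NULL` skips filtering.
#' @param lag `"zero"` (default) or `"max"`.
#' @param max_lag Lag search half-width in seconds for `lag = "max"`.
#' @return An object of class `correlation_report`: list with `pair_r`
#'   (vector over distinct pairs), `max_r`, `mean_r`, `band`,
#'   `lag_convention`, `n_signals`.
#' @export
pair_correlations <- function(x, fs, cutoff = 0.1,
                              lag = c("zero", "max"), max_lag = 10) {
  lag <- match.arg(lag)
  if (!is.matrix(x) || nrow(x) < 2)
    stop("pair_correlations: need a matrix with at least 2 signals")
  if (!is.null(cutoff)) x <- lowpass(x, fs, cutoff)
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warning("pair_correlations: ", sum(sds == 0),
            " constant signal(s) excluded (undefined correlation)")
    x <- x[sds > 0, , drop = FALSE]
    if (nrow(x) < 2) stop("pair_correlations: fewer than 2 non-constant signals")
  }
  if (lag == "zero") {
    cm <- stats::cor(t(x))
    pair_r <- cm[upper.tri(cm)]
  } else {
    shift_max <- round(max_lag * fs)
    n <- nrow(x)
    pair_r <- c()
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      cc <- stats::ccf(x[i, ], x[j, ], lag.max = shift_max, plot = FALSE)
      pair_r <- c(pair_r, max(cc$acf))
    }
  }
  structure(list(pair_r = pair_r, max_r = max(pair_r), mean_r = mean(pair_r),
                 band = if (is.null(cutoff)) NULL else c(0, cutoff),
                 lag_convention = lag, n_signals = nrow(x)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Pair correlations over %d signals (%d pairs, %s lag): max_r = %.3f, mean_r = %.3f\n",
              x$n_signals, length(x$pair_r), x$lag_convention,
              x$max_r, x$mean_r))
  invisible(x)
}

#' Spectra of mean auto- and cross-correlation curves across two
#' disjoint unit samples
#'
#' Follows the correlation-curve convention: Pearson-normalized
#' time-lagged autocorrelation curves are computed for each unit of the
#' first sample and averaged; cross-correlation curves are computed for
#' every pair spanning the two samples and averaged (incoherent
#' fluctuations cancel in the mean curve). The Welch PSD of each mean
#' curve, taken as a lag-domain signal at the original sampling rate, is
#' returned. On this scale the spectrum of the autocorrelation curve of
#' a Lorentzian process keeps its knee frequency, and the auto/cross
#' band-power ratio is the square of the underlying coherent amplitude
#' ratio. Near criticality the shared slow mode drives the
#' cross-spectrum toward the auto-spectrum at the lowest frequencies.
#'
#' @param sample_a Matrix of unit traces (one unit per row), first sample.
#' @param sample_b Matrix of unit traces, second (disjoint) sample.
#' @param fs Sampling rate, Hz.
#' @param segment_length,overlap,scale_k Welch settings, see
#'   [welch_psd()].
#' @param max_lag Correlation-curve half-width, seconds (default 200);
#'   clipped to the signal length.
#' @param cutoff Optional low-pass cutoff (Hz) applied to every trace
#'   before the correlation curves, isolating the slow fluctuations the
#'   calibration targets (default 0.1; `NULL` disables, for broadband
#'   spectral-shape uses).
#' @return List with elements `auto` and `cross`, both
#'   `spectrum_estimate`s on a common grid.
#' @export
auto_cross_psd <- function(sample_a, sample_b, fs, segment_length = 4096,
                           overlap = 0.5, scale_k = 1, max_lag = 200,
                           cutoff = 0.1) {
  stopifnot(is.matrix(sample_a), is.matrix(sample_b),
            ncol(sample_a) == ncol(sample_b))
  if (!is.null(cutoff)) {
    sample_a <- lowpass(sample_a, fs, cutoff)
    sample_b <- lowpass(sample_b, fs, cutoff)
  }
  n <- ncol(sample_a)
  lag_n <- min(round(max_lag * fs), n - 1)
  # FFT-based correlation curves, shared zero-padded length
  npad <- 2^ceiling(log2(2 * n))
  ffts <- function(m) {
    mc <- m - rowMeans(m)
    list(f = apply(mc, 1, function(v) stats::fft(c(v, numeric(npad - n)))),
         sd = sqrt(rowMeans(mc^2)))
  }
  fa <- ffts(sample_a)
  fb <- ffts(sample_b)
  curve_of <- function(Fx, Fy, sx, sy) {
    cc <- Re(stats::fft(Fx * Conj(Fy), inverse = TRUE)) / npad
    # lags 0..lag_n then -lag_n..-1 (circular layout of the linear sums)
    c(cc[(npad - lag_n + 1):npad], cc[1:(lag_n + 1)]) / (n * sx * sy)
  }
  na <- nrow(sample_a)
  nb <- nrow(sample_b)
  auto_curve <- 0
  for (i in seq_len(na))
    auto_curve <- auto_curve + curve_of(fa$f[, i], fa$f[, i],
                                        fa$sd[i], fa$sd[i])
  auto_curve <- auto_curve / na
  cross_curve <- 0
  for (i in seq_len(na)) for (j in seq_len(nb))
    cross_curve <- cross_curve + curve_of(fa$f[, i], fb$f[, j],
                                          fa$sd[i], fb$sd[j])
  cross_curve <- cross_curve / (na * nb)
  seg <- min(segment_length, 2^floor(log2(length(auto_curve) / 1.5)))
  auto <- welch_psd(auto_curve, fs, seg, overlap, scale_k)
  cross <- welch_psd(cross_curve, fs, seg, overlap, scale_k)
  list(auto = auto, cross = cross)
}

#' Band power and spectral ratios
#'
#' `band_power()` is the mean power over bins inside `band`.
#' `log_power_ratio()` is `log10(band_power(auto) / band_power(cross))`,
#' the statistic used to calibrate the operating point against the
#' empirical low-frequency auto/cross ratio. `slow_fast_ratio()` divides
#' slow-band by fast-band power of one spectrum, the normalized
#' slow-power measure used in the size-by-gain analyses.
#'
#' @param spectrum,auto,cross `spectrum_estimate` objects.
#' @param band,slow_band,fast_band Length-2 numeric `c(lo, hi)` in Hz;
#'   bins with `lo <= f <= hi` are used and the band must contain at
#'   least one bin.
#' @return A scalar.
#' @export
band_power <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "spectrum_estimate"))
  idx <- band_bins(spectrum$freqs, band)
  mean(spectrum$power[idx])
}

#' @rdname band_power
#' @export
log_power_ratio <- function(auto, cross, band = c(0.01, 0.1)) {
  log10(band_power(auto, band) / band_power(cross, band))
}

#' @rdname band_power
#' @export
slow_fast_ratio <- function(spectrum, slow_band = c(0.01, 0.1),
                            fast_band = c(1, 10)) {
  band_power(spectrum, slow_band) / band_power(spectrum, fast_band)
}

band_bins <- function(freqs, band) {
  if (length(band) != 2 || band[1] >= band[2])
    stop("band must be c(lo, hi) with lo < hi")
  idx <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(idx))
    stop(sprintf("band [%g, %g] Hz contains no frequency bins", band[1], band[2]))
  idx
}
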