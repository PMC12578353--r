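#' Specification of surrogate empirical-like signals
#'
#' Describes synthetic stand-ins for the empirical high-frequency
#' broadband (HFB) recordings that the calibration stages assume: a
#' two-regime power-law spectrum with a smooth knee, a target pairwise
#' correlation of the slow (< 0.1 Hz) fluctuations between channels, and
#' a target low-frequency auto-to-cross log power ratio. Defaults mirror
#' the empirical description: knee near 1 Hz, inter-channel correlation
#' 0.56, log ratio 0.84.
#'
#' @param low_exp Power-law exponent below the knee (<= 0).
#' @param high_exp Power-law exponent above the knee (<= 0).
#' @param knee Knee frequency, Hz.
#' @param amplitude Spectrum amplitude at 1 Hz in the low-frequency
#'   regime's units.
#' @param r_target Target Pearson correlation of < 0.1 Hz fluctuations
#'   between the two channels of [surrogate_pair()], in (-1, 1).
#' @param log_ratio_target Target log10 auto/cross low-band power ratio
#'   of the bundle's sample sets.
#' @param duration Seconds of signal to generate.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed.
#' @return An object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(low_exp = -0.5, high_exp = -2, knee = 1,
                           amplitude = 1, r_target = 0.56,
                           log_ratio_target = 0.84, duration = 1200,
                           fs = 250, seed = 1) {
  if (low_exp > 0 || high_exp > 0)
    stop("surrogate_spec: exponents must be <= 0")
  if (knee <= 0) stop("surrogate_spec: knee must be positive")
  if (abs(r_target) >= 1)
    stop("surrogate_spec: r_target must lie in (-1, 1)")
  if (amplitude <= 0) stop("surrogate_spec: amplitude must be positive")
  structure(list(low_exp = low_exp, high_exp = high_exp, knee = knee,
                 amplitude = amplitude, r_target = r_target,
                 log_ratio_target = log_ratio_target, duration = duration,
                 fs = fs, seed = seed),
            class = "surrogate_spec")
}

#' Deterministic two-regime surrogate spectrum
#'
#' Evaluates the smooth two-regime power law
#' \deqn{S(f) = A f^{a_{low}} (1 + (f/f_{knee})^2)^{(a_{high}-a_{low})/2}}
#' which follows exponent `a_low` well below the knee and `a_high` well
#' above it.
#'
#' @param spec A [surrogate_spec()].
#' @param freqs Frequency grid in Hz; default a Welch-like grid from
#'   `1/duration` to `fs/2`.
#' @return A `spectrum_estimate` with the analytic curve as power.
#' @export
surrogate_spectrum <- function(spec, freqs = NULL) {
  stopifnot(inherits(spec, "surrogate_spec"))
  if (is.null(freqs))
    freqs <- seq(1 / spec$duration, spec$fs / 2, by = 1 / spec$duration)
  power <- surrogate_shape(spec, freqs)
  structure(list(freqs = freqs, power = power, fs = spec$fs,
                 segment_length = NA, overlap = NA, window = "analytic",
                 scale_k = 1, n_segments = NA),
            class = "spectrum_estimate")
}

surrogate_shape <- function(spec, f) {
  spec$amplitude * f^spec$low_exp *
    (1 + (f / spec$knee)^2)^((spec$high_exp - spec$low_exp) / 2)
}

# Spectrally shaped Gaussian series: white noise filtered in the
# frequency domain by sqrt of the target one-sided density.
shaped_series <- function(spec, n) {
  z <- stats::rnorm(n)
  zf <- stats::fft(z)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) * spec$fs / n  # two-sided |f| grid
  h <- numeric(n)
  pos <- f > 0
  h[pos] <- sqrt(surrogate_shape(spec, f[pos]) * spec$fs / 2)
  h[1] <- 0  # zero mean
  Re(stats::fft(zf * h, inverse = TRUE)) / n
}

#' Correlated surrogate channel pair
#'
#' Generates two channels as a shared-component mixture,
#' `ch = sqrt(w) * common + sqrt(1 - w) * independent`, all components
#' spectrally shaped to the surrogate spectrum. Because every component
#' shares one spectral shape, the mixing weight equals the expected
#' Pearson correlation in any band, so `w = r_target`.
#'
#' @param spec A [surrogate_spec()].
#' @return Matrix `2 x n` of the two channels, with attribute `fs`.
#' @export
surrogate_pair <- function(spec) {
  stopifnot(inherits(spec, "surrogate_spec"))
  if (spec$r_target < 0)
    stop("surrogate_pair: negative r_target is not representable by this mixture")
  set.seed(spec$seed)
  n <- round(spec$duration * spec$fs)
  w <- spec$r_target
  common <- shaped_series(spec, n)
  out <- rbind(sqrt(w) * common + sqrt(1 - w) * shaped_series(spec, n),
               sqrt(w) * common + sqrt(1 - w) * shaped_series(spec, n))
  attr(out, "fs") <- spec$fs
  out
}

#' Write a full surrogate bundle to disk
#'
#' Produces the file set consumed by the calibration pipeline in place of
#' empirical recordings: the correlated channel pair, its estimated
#' spectra, and auto/cross spectra from two disjoint channel samples
#' whose between-sample shared weight is chosen so the realized low-band
#' auto/cross log power ratio (on the correlation-curve PSD scale of
#' [auto_cross_psd()]) sits near `log_ratio_target`. A JSON manifest
#' records the spec and the realized statistics.
#'
#' @param spec A [surrogate_spec()].
#' @param out_dir Output directory (created if missing).
#' @param n_per_sample Channels per sample set (default 6; small sets
#'   leave the realized cross spectrum noise-limited and compress the
#'   realized ratio below target).
#' @return Invisibly, the manifest as a list (also written to
#'   `manifest.json`): realized pair correlation, realized log ratio,
#'   file names, seed.
#' @export
surrogate_bundle <- function(spec, out_dir, n_per_sample = 6) {
  stopifnot(inherits(spec, "surrogate_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pair <- surrogate_pair(spec)
  fs <- spec$fs
  n <- ncol(pair)
  utils::write.csv(data.frame(time_s = (seq_len(n) - 1) / fs,
                              ch1 = pair[1, ], ch2 = pair[2, ]),
                   file.path(out_dir, "pair.csv"), row.names = FALSE)
  r_realized <- pair_correlations(pair, fs, cutoff = 0.1)$mean_r

  seg <- min(32768, 2^floor(log2(n / 4)))
  sp1 <- welch_psd(pair[1, ], fs, segment_length = seg)
  write_spectrum(sp1, file.path(out_dir, "pair_psd.csv"))
  write_spectrum(surrogate_spectrum(spec),
                 file.path(out_dir, "analytic_spectrum.csv"))

  # two disjoint samples with between-sample shared weight set by the
  # log-ratio target; the auto/cross estimator works on the squared
  # (correlation-curve PSD) scale, so the amplitude weight is
  # 10^(-target/2)
  w_x <- 10^(-spec$log_ratio_target / 2)
  set.seed(spec$seed + 1)
  common <- shaped_series(spec, n)
  make_set <- function() {
    t(vapply(seq_len(n_per_sample), function(i)
      sqrt(w_x) * common + sqrt(1 - w_x) * shaped_series(spec, n),
      numeric(n)))
  }
  a <- make_set()
  b <- make_set()
  ac <- auto_cross_psd(a, b, fs, segment_length = seg)
  write_spectrum(ac$auto, file.path(out_dir, "auto_psd.csv"))
  write_spectrum(ac$cross, file.path(out_dir, "cross_psd.csv"))
  lr <- log_power_ratio(ac$auto, ac$cross, c(0.01, 0.1))

  manifest <- list(spec = unclass(spec),
                   realized_pair_correlation = r_realized,
                   realized_log_ratio = lr,
                   n_per_sample = n_per_sample,
                   files = c("pair.csv", "pair_psd.csv",
                             "analytic_spectrum.csv", "auto_psd.csv",
                             "cross_psd.csv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
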