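#' Welch power spectral density estimate
#'
#' Averaged modified periodogram with a Hann window, 50% overlap by
#' default, and one-sided density scaling so that for a zero-mean signal
#' `sum(power) * df` approximates the signal variance (Parseval). The
#' default applies no detrending (`detrend = "none"`), so a nonzero
#' baseline contributes leakage to the lowest bins — deliberately: the
#' recall-related baseline shift, amplified by the near-critical DC gain,
#' expresses itself in exactly those ultra-slow bins. Pass
#' `detrend = "constant"` to remove each segment's mean instead.
#' The free amplitude factor `scale_k` multiplies the density; it is the
#' scaling used when matching simulated spectra against externally scaled
#' reference spectra, and is recorded in the estimate's metadata.
#'
#' Two segment-length regimes are used throughout the analyses:
#' `2^12` samples (~16 s at 250 Hz) for mid/high-frequency bands, and a
#' long-segment mode (`2^15` samples, ~131 s) when ultra-slow bands below
#' 0.2 Hz must be resolved.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate, Hz.
#' @param segment_length Samples per segment (default `2^12`); shortened
#'   to the signal length if needed, but the signal must span at least
#'   two (overlapping) segments.
#' @param overlap Fractional overlap in `[0, 1)` (default 0.5).
#' @param scale_k Positive amplitude scaling factor (default 1).
#' @param window Taper: `"hann"` or `"rect"`.
#' @param detrend `"none"` (default) or `"constant"` (per-segment mean
#'   removal).
#' @return An object of class `spectrum_estimate`: list with `freqs`,
#'   `power`, `fs`, `segment_length`, `overlap`, `window`, `scale_k`,
#'   `n_segments`. The zero-frequency bin is dropped.
#' @export
welch_psd <- function(x, fs, segment_length = 4096, overlap = 0.5,
                      scale_k = 1, window = c("hann", "rect"),
                      detrend = c("none", "constant")) {
  window <- match.arg(window)
  detrend <- match.arg(detrend)
  if (scale_k <= 0) stop("welch_psd: scale_k must be positive")
  x <- as.numeric(x)
  n <- length(x)
  step <- max(1, round(segment_length * (1 - overlap)))
  if (n < segment_length + step)
    stop("welch_psd: signal must span at least two segments (need ",
         segment_length + step, " samples, have ", n, ")")
  segs <- welch_segments(n, segment_length, step)
  w <- if (window == "hann") hann_window(segment_length) else rep(1, segment_length)
  u <- sum(w^2)
  nf <- segment_length %/% 2
  acc <- numeric(nf)
  for (s in segs) {
    seg <- x[s:(s + segment_length - 1)]
    if (detrend == "constant") seg <- seg - mean(seg)
    sp <- stats::fft(seg * w)[2:(nf + 1)]
    acc <- acc + (Mod(sp)^2)
  }
  pw <- acc / length(segs) / (fs * u)
  # one-sided: double all bins except Nyquist (present iff even length)
  dbl <- rep(2, nf)
  dbl[nf] <- if (segment_length %% 2 == 0) 1 else 2
  pw <- pw * dbl * scale_k
  structure(list(freqs = fs * seq_len(nf) / segment_length, power = pw,
                 fs = fs, segment_length = segment_length,
                 overlap = overlap, window = window, scale_k = scale_k,
                 n_segments = length(segs)),
            class = "spectrum_estimate")
}

welch_segments <- function(n, segment_length, step) {
  starts <- seq(1, n - segment_length + 1, by = step)
  starts
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf("Spectrum estimate: %d bins, %.4g-%.4g Hz, %s window, %d segments of %d samples, k = %g\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$window,
              x$n_segments, x$segment_length, x$scale_k))
  invisible(x)
}

#' Write a spectrum estimate to CSV with a JSON metadata sidecar
#'
#' @param spec A `spectrum_estimate`.
#' @param path CSV path (columns `freq_hz`, `power`); metadata goes to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum_estimate"))
  utils::write.csv(data.frame(freq_hz = spec$freqs, power = spec$power),
                   path, row.names = FALSE)
  meta <- spec[c("fs", "segment_length", "overlap", "window", "scale_k",
                 "n_segments")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  d <- utils::read.csv(path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  structure(list(freqs = d$freq_hz, power = d$power,
                 fs = meta$fs %||% NA_real_,
                 segment_length = meta$segment_length %||% NA,
                 overlap = meta$overlap %||% NA, window = meta$window %||% NA,
                 scale_k = meta$scale_k %||% 1,
                 n_segments = meta$n_segments %||% NA),
            class = "spectrum_estimate")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
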