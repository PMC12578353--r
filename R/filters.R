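#' Zero-phase Butterworth filtering
#'
#' `lowpass()` applies a zero-phase (forward-backward) Butterworth
#' low-pass, the filter used to isolate ultra-slow (< 0.1 Hz) fluctuations
#' before correlation analysis. `highpass()` is the analogous high-pass
#' used to reshape input-noise spectra. Both operate along time; a matrix
#' is filtered row-wise (rows = units/channels).
#'
#' Very low cutoffs relative to the sampling rate make transfer-function
#' IIR coefficients ill-conditioned, so the design is applied as a cascade
#' of second-order sections derived from the analog Butterworth prototype
#' by bilinear transform.
#'
#' @param x Numeric vector, or matrix with one signal per row.
#' @param fs Sampling rate, Hz.
#' @param cutoff Cutoff frequency, Hz; must be below `fs / 2`.
#' @param order Filter order (default 4).
#' @return Filtered data with the shape of `x`.
#' @export
lowpass <- function(x, fs, cutoff = 0.1, order = 4) {
  butter_filtfilt(x, fs, cutoff, order, type = "low")
}

#' @rdname lowpass
#' @export
highpass <- function(x, fs, cutoff, order = 4) {
  butter_filtfilt(x, fs, cutoff, order, type = "high")
}

# Butterworth cascade of second-order sections (plus one first-order
# section for odd orders): analog prototype poles mapped by the bilinear
# transform with frequency pre-warping.
butter_sos <- function(fs, cutoff, order, type = c("low", "high")) {
  type <- match.arg(type)
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= fs / 2)
    stop("butterworth: cutoff must lie in (0, fs/2)")
  if (order < 1 || order != round(order))
    stop("butterworth: order must be a positive integer")
  warped <- 2 * fs * tan(pi * cutoff / fs)
  sections <- list()
  k <- seq_len(floor(order / 2))
  if (length(k)) {
    theta <- pi / 2 + pi * (2 * k - 1) / (2 * order)
    for (th in theta) {
      p <- complex(real = cos(th), imaginary = sin(th))
      pa <- if (type == "low") warped * p else warped / p
      sections[[length(sections) + 1]] <- bilinear_biquad(pa, FALSE, fs, type)
    }
  }
  if (order %% 2 == 1) {
    sections[[length(sections) + 1]] <- bilinear_biquad(-warped, TRUE, fs, type)
  }
  sections
}

# Map one analog pole (or conjugate pair) to a digital biquad via
# s = 2*fs*(z-1)/(z+1). Unity passband gain per section.
bilinear_biquad <- function(pa, real_pole, fs, type) {
  c2 <- 2 * fs
  if (real_pole) {
    pa <- Re(pa)
    d0 <- c2 - pa
    if (type == "low") {
      b <- c(-pa, -pa, 0) / d0
    } else {
      b <- c(c2, -c2, 0) / d0
    }
    a <- c(1, (-c2 - pa) / d0, 0)
  } else {
    B <- -2 * Re(pa)
    C <- Mod(pa)^2
    d0 <- c2^2 + B * c2 + C
    d1 <- 2 * C - 2 * c2^2
    d2 <- c2^2 - B * c2 + C
    if (type == "low") {
      b <- C * c(1, 2, 1) / d0
    } else {
      b <- c2^2 * c(1, -2, 1) / d0
    }
    a <- c(1, d1 / d0, d2 / d0)
  }
  list(b = b, a = a)
}

# Run the biquad cascade over the columns of x (initial-rest state);
# stats::filter vectorizes over columns in C.
sos_filter <- function(sections, x) {
  n <- nrow(x)
  for (s in sections) {
    nb <- if (s$a[3] == 0 && s$b[3] == 0) 2L else 3L
    xp <- rbind(matrix(0, nb - 1, ncol(x)), x)
    xm <- stats::filter(xp, s$b[1:nb], method = "convolution", sides = 1)
    xm <- xm[nb:(n + nb - 1), , drop = FALSE]
    x <- matrix(as.numeric(stats::filter(xm, -s$a[2:nb], method = "recursive")),
                n, ncol(x))
  }
  x
}

# One filtering pass with the initial-rest transient neutralized: the
# cascade runs on the deviation from each column's first value, and the
# DC response of that value (1 for low-pass, 0 for high-pass) is added
# back, so a constant input passes a low-pass exactly unchanged.
sos_pass <- function(sections, x, type) {
  x0 <- x[1, ]
  y <- sos_filter(sections, sweep(x, 2, x0))
  if (type == "low") y <- sweep(y, 2, x0, `+`)
  y
}

# Zero-phase application: forward-backward pass with reflective padding
# to suppress edge transients. Signals arrive as rows, are processed as
# columns.
butter_filtfilt <- function(x, fs, cutoff, order, type) {
  sections <- butter_sos(fs, cutoff, order, type)
  mat_in <- is.matrix(x)
  xm <- if (mat_in) t(x) else matrix(as.numeric(x), ncol = 1)
  n <- nrow(xm)
  if (n < 3) stop("butterworth: signal too short")
  npad <- min(n - 1, max(100, round(3 * fs / cutoff)))
  top <- 2 * matrix(xm[1, ], npad, ncol(xm), byrow = TRUE) -
    xm[(npad + 1):2, , drop = FALSE]
  bot <- 2 * matrix(xm[n, ], npad, ncol(xm), byrow = TRUE) -
    xm[(n - 1):(n - npad), , drop = FALSE]
  y <- sos_pass(sections, rbind(top, xm, bot), type)
  y <- sos_pass(sections, y[nrow(y):1, , drop = FALSE], type)
  y <- y[nrow(y):1, , drop = FALSE][(npad + 1):(npad + n), , drop = FALSE]
  if (mat_in) t(y) else y[, 1]
}
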