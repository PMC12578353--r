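#' Generate an external-drive matrix
#'
#' Realizes the noisy external input as an `n_units x n_steps` matrix:
#' independent normal draws per unit per integration step, scaled to
#' `(mean, sd)`, plus `dc_offset`. When the spec carries a filter, the
#' zero-mean fluctuating part is reshaped by the zero-phase Butterworth
#' filter along time before the mean and offset are restored, so the
#' marginal mean is preserved and only the temporal correlation structure
#' of the drive changes.
#'
#' Note that in-loop white noise inside [simulate_rates()] is the
#' memory-light equivalent of the unfiltered case; this function is the
#' route for spectrally shaped drives (and for inspecting the drive's own
#' spectrum).
#'
#' @param spec A [noise_spec()].
#' @param n_units Number of units (rows).
#' @param n_steps Number of integration steps (columns).
#' @param dt Integration step in seconds (sets the sampling rate
#'   `1 / dt` used by the filter design).
#' @return A numeric matrix `n_units x n_steps`.
#' @export
make_drive <- function(spec, n_units, n_steps, dt = 0.001) {
  stopifnot(inherits(spec, "noise_spec"))
  if (n_steps < 1) stop("make_drive: n_steps must be >= 1")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  z <- matrix(stats::rnorm(n_units * n_steps, 0, spec$sd), n_units, n_steps)
  if (!is.null(spec$filter)) {
    fs <- 1 / dt
    z <- butter_filtfilt(z, fs, spec$filter$cutoff, spec$filter$order,
                         spec$filter$type)
  }
  z + spec$mean + spec$dc_offset
}
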