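#' Form iEEG-like proxy signals by partial summation
#'
#' The simulated electrode signal is the summed activity of
#' `max(1, round(alpha * N))` randomly chosen units, standing in for the
#' local population sampled by a recording contact. When two samples are
#' requested they are drawn disjoint, matching the convention that
#' auto-spectra are estimated from the first sample only and cross-spectra
#' across pairs spanning the two samples.
#'
#' @param traces A `rate_traces` object.
#' @param spec A [proxy_spec()]; its seed fixes the unit draw.
#' @return An object of class `proxy_signals`: list with `proxies` (a
#'   matrix, one summed signal per row), `sample_ids` (list of integer
#'   vectors of unit indices), `unit_traces` (list of matrices of the
#'   sampled units' traces), `fs` and `spec`.
#' @export
ieeg_proxy <- function(traces, spec = proxy_spec()) {
  stopifnot(inherits(traces, "rate_traces"), inherits(spec, "proxy_spec"))
  n <- nrow(traces$values)
  k <- max(1L, as.integer(round(spec$alpha * n)))
  if (spec$n_samples * k > n)
    stop("ieeg_proxy: cannot draw ", spec$n_samples, " disjoint samples of ",
         k, " units from ", n)
  if (spec$alpha * n < 1)
    warning("ieeg_proxy: alpha * N < 1; sample size raised to 1 unit")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  ids <- sample.int(n, spec$n_samples * k)
  sample_ids <- split(ids, rep(seq_len(spec$n_samples), each = k))
  names(sample_ids) <- NULL
  unit_traces <- lapply(sample_ids, function(i)
    traces$values[i, , drop = FALSE])
  proxies <- do.call(rbind, lapply(unit_traces, colSums))
  structure(list(proxies = proxies, sample_ids = sample_ids,
                 unit_traces = unit_traces, fs = traces$fs, spec = spec),
            class = "proxy_signals")
}
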