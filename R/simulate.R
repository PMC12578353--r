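#' Integrate the rate dynamics of the recurrent network
#'
#' Forward-Euler integration of the rectified-linear rate model
#' \deqn{\tau \frac{dr_j}{dt} = -r_j + \gamma\left[\sum_k W_{jk} r_k +
#' I^{ext}_j(t)\right]_+}
#' where the bracket denotes a rectified-linear transfer. With a
#' nonnegative initial state the rates stay nonnegative at every step.
#' The state is integrated at `params$dt` and decimated to `fs_out` for
#' storage and analysis.
#'
#' The drive is either a [noise_spec()] — white noise drawn independently
#' per unit per integration step, generated inside the integration loop;
#' when the spec carries a filter, the zero-mean fluctuation is shaped by
#' the Butterworth cascade applied twice (matching the magnitude response
#' of a zero-phase application) before the mean is restored — or a
#' pre-computed `n_units x n_steps` matrix such as one from
#' [make_drive()].
#'
#' Rates exceeding `overflow_guard` abort with a supercritical-runaway
#' error: a bounded near-critical simulation never approaches the guard.
#'
#' @param W A `weight_matrix` from [build_weights()], or a plain square
#'   matrix (then `params` supplies gain/tau/dt).
#' @param params A [network_params()] object.
#' @param drive A [noise_spec()] or a numeric matrix `n_units x n_steps`.
#' @param duration Simulated time, seconds.
#' @param initial_state Nonnegative rate vector (default all zeros).
#' @param fs_out Output sampling rate, Hz (default 250); must divide
#'   `1 / dt` evenly.
#' @param overflow_guard Abort threshold on any rate (default `1e6`).
#' @return An object of class `rate_traces`: list with `values`
#'   (units x timepoints), `fs`, `t_start`, `params`, `input_meta`.
#' @export
simulate_rates <- function(W, params = NULL, drive = noise_spec(),
                           duration, initial_state = NULL, fs_out = 250,
                           overflow_guard = 1e6) {
  if (inherits(W, "weight_matrix")) {
    if (is.null(params)) params <- W$params
    W <- W$weights
  }
  if (is.null(params)) stop("simulate_rates: params required for a plain matrix")
  n <- nrow(W)
  if (n != params$n_units)
    stop("simulate_rates: weight matrix size does not match params$n_units")
  dt <- params$dt
  keep_every <- round(1 / (dt * fs_out))
  if (abs(keep_every - 1 / (dt * fs_out)) > 1e-8)
    stop("simulate_rates: fs_out must be an integer divisor of 1/dt")
  n_steps <- round(duration / dt)
  if (n_steps < keep_every) stop("simulate_rates: duration too short")
  if (is.null(initial_state)) initial_state <- rep(0, n)
  if (length(initial_state) != n || any(initial_state < 0))
    stop("simulate_rates: initial_state must be a nonnegative vector of length N")

  # transpose: the kernel wants W in row-major (gather) layout
  Wsp <- Matrix::Matrix(t(W), sparse = TRUE)

  # anti-alias filter applied to the state before decimation; spectra are
  # analyzed within the passband (below ~0.4 * fs_out)
  if (keep_every > 1) {
    secs <- butter_sos(1 / dt, 0.45 * fs_out, 8, "low")
    sos_b <- do.call(rbind, lapply(secs, `[[`, "b"))
    sos_a <- do.call(rbind, lapply(secs, `[[`, "a"))
  } else {
    sos_b <- sos_a <- matrix(0, 0, 3)
  }

  if (inherits(drive, "noise_spec")) {
    # a fixed spec seed pins the stream; otherwise one is drawn from the
    # R RNG so that set.seed() upstream controls the whole run
    noise_seed <- if (!is.null(drive$seed)) drive$seed
                  else sample.int(.Machine$integer.max, 1)
    if (is.null(drive$filter)) {
      nsb <- nsa <- matrix(0, 0, 3)
      meta <- sprintf("white noise mean %.3g pA, sd %.3g pA, dc %.3g pA",
                      drive$mean, drive$sd, drive$dc_offset)
    } else {
      # the cascade is applied twice so the magnitude response matches a
      # zero-phase (forward-backward) application of the same design;
      # phase is irrelevant for stationary noise
      nsecs <- butter_sos(1 / dt, drive$filter$cutoff, drive$filter$order,
                          drive$filter$type)
      nsecs <- c(nsecs, nsecs)
      nsb <- do.call(rbind, lapply(nsecs, `[[`, "b"))
      nsa <- do.call(rbind, lapply(nsecs, `[[`, "a"))
      meta <- sprintf("filtered noise mean %.3g pA, sd %.3g pA, dc %.3g pA, %s-pass %g Hz order %d",
                      drive$mean, drive$sd, drive$dc_offset,
                      drive$filter$type, drive$filter$cutoff,
                      drive$filter$order)
    }
    vals <- sim_euler_cpp(Wsp, params$gain, params$tau, dt, n_steps,
                          keep_every, initial_state, TRUE,
                          drive$mean + drive$dc_offset, drive$sd,
                          noise_seed, matrix(0, 0, 0), nsb, nsa,
                          sos_b, sos_a, overflow_guard)
  } else if (is.matrix(drive)) {
    if (nrow(drive) != n || ncol(drive) < n_steps)
      stop("simulate_rates: drive matrix must be n_units x n_steps")
    vals <- sim_euler_cpp(Wsp, params$gain, params$tau, dt, n_steps,
                          keep_every, initial_state, FALSE, 0, 0, 0,
                          drive, matrix(0, 0, 3), matrix(0, 0, 3),
                          sos_b, sos_a, overflow_guard)
    meta <- "user-supplied drive matrix"
  } else {
    stop("simulate_rates: drive must be a noise_spec or a matrix")
  }

  structure(list(values = vals, fs = fs_out, t_start = 0,
                 params = params, input_meta = meta),
            class = "rate_traces")
}

#' @export
print.rate_traces <- function(x, ...) {
  cat(sprintf("Rate traces: %d units x %d samples at %g Hz (%.1f s), t_start = %g s\n",
              nrow(x$values), ncol(x$values), x$fs,
              ncol(x$values) / x$fs, x$t_start))
  cat("  drive: ", x$input_meta, "\n", sep = "")
  invisible(x)
}

#' Drop an initial stretch of a simulation
#'
#' @param traces A `rate_traces` object.
#' @param discard Seconds to remove from the start.
#' @return The shortened `rate_traces` with `t_start` advanced.
#' @export
discard_burnin <- function(traces, discard) {
  stopifnot(inherits(traces, "rate_traces"))
  n_drop <- round(discard * traces$fs)
  if (n_drop >= ncol(traces$values))
    stop("discard_burnin: discard longer than the trace")
  if (n_drop > 0) traces$values <- traces$values[, -seq_len(n_drop), drop = FALSE]
  traces$t_start <- traces$t_start + n_drop / traces$fs
  traces
}
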