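#' Generative constants of the random recurrent rate network
#'
#' Bundles every parameter of the network model: size, connection
#' statistics, the slope of the f-I curve, the characteristic integration
#' time, and the Euler step. Defaults are the reference configuration used
#' throughout the analyses: a 240-unit network with sparse connectivity
#' (`p = 0.2`), nonzero weights drawn from a normal law with mean
#' `conn_mean / N` and SD `conn_sd / N`, and a 20 ms time constant close to
#' the cortical membrane time constant.
#'
#' The dimensionless control parameter `G = gain * sparseness * conn_mean`
#' measures proximity to the critical point at `G = 1`; with the defaults
#' `G = 0.1 * 0.2 * 49.881 ~ 1`.
#'
#' @param n_units Number of rate units (N), at least 2.
#' @param sparseness Connection probability `p` in \eqn{[0, 1]}.
#' @param conn_mean Mean of nonzero connection strengths before the `1/N`
#'   normalization, in pA/Hz.
#' @param conn_sd SD of nonzero connection strengths before the `1/N`
#'   normalization, in pA/Hz.
#' @param gain Slope `gamma` of the rectified-linear f-I curve, Hz/pA.
#' @param tau Characteristic integration time, seconds.
#' @param dt Euler integration step, seconds; must satisfy `dt <= tau / 10`.
#' @param seed Optional integer seed used when realizing the weight matrix.
#' @return An object of class `network_params`.
#' @examples
#' p <- network_params()
#' control_parameter(p$gain, p$sparseness, p$conn_mean)
#' @export
network_params <- function(n_units = 240, sparseness = 0.2,
                           conn_mean = 49.881, conn_sd = 4.988,
                           gain = 0.1, tau = 0.020, dt = 0.001,
                           seed = NULL) {
  num <- c(n_units = n_units, sparseness = sparseness, conn_mean = conn_mean,
           conn_sd = conn_sd, gain = gain, tau = tau, dt = dt)
  if (!all(is.finite(num)))
    stop("network_params: all parameters must be finite numbers")
  if (n_units < 2 || n_units != round(n_units))
    stop("network_params: n_units must be an integer >= 2")
  if (sparseness < 0 || sparseness > 1)
    stop("network_params: sparseness must lie in [0, 1]")
  if (tau <= 0 || dt <= 0)
    stop("network_params: tau and dt must be positive")
  if (dt > tau / 10 + 1e-12)
    stop("network_params: dt must not exceed tau / 10")
  if (conn_sd < 0) stop("network_params: conn_sd must be nonnegative")
  g <- gain * sparseness * conn_mean
  if (!is.finite(g) || g < 0)
    stop("network_params: control parameter gain*sparseness*conn_mean must be finite and >= 0")
  structure(list(n_units = as.integer(n_units), sparseness = sparseness,
                 conn_mean = conn_mean, conn_sd = conn_sd, gain = gain,
                 tau = tau, dt = dt, seed = seed),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf("Network parameters: N = %d, p = %.3g, mu_conn = %.4g pA/Hz, sigma_conn = %.4g pA/Hz\n",
              x$n_units, x$sparseness, x$conn_mean, x$conn_sd))
  cat(sprintf("  gain = %.5g Hz/pA, tau = %.3g s, dt = %.3g s, G = %.4f\n",
              x$gain, x$tau, x$dt,
              control_parameter(x$gain, x$sparseness, x$conn_mean)))
  invisible(x)
}

#' Specification of the noisy external drive
#'
#' The background drive is white noise: one independent normal draw per
#' unit per integration step, held constant within the step. `dc_offset`
#' is the additive constant current (`I_add`) used to emulate the
#' recall-related baseline shift; `filter`, when present, reshapes the
#' fluctuating part of the drive with a zero-phase Butterworth high-pass
#' before the mean and offset are restored, so only the temporal
#' correlation structure changes.
#'
#' @param mean Baseline of the external current, pA (default 20).
#' @param sd SD of the per-step noise, pA (default 11.5).
#' @param dc_offset Additive constant current `I_add`, pA (default 0).
#' @param filter Optional list `list(cutoff = , order = , type = "high")`
#'   describing a Butterworth filter applied to the noise fluctuations.
#' @param seed Optional integer seed for drawing the noise.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(mean = 20, sd = 11.5, dc_offset = 0,
                       filter = NULL, seed = NULL) {
  if (!is.finite(mean) || !is.finite(sd) || !is.finite(dc_offset))
    stop("noise_spec: mean, sd and dc_offset must be finite")
  if (sd < 0) stop("noise_spec: sd must be nonnegative")
  if (!is.null(filter)) {
    if (is.null(filter$cutoff) || !is.finite(filter$cutoff) || filter$cutoff <= 0)
      stop("noise_spec: filter cutoff must be a positive frequency in Hz")
    if (is.null(filter$order)) filter$order <- 4
    if (is.null(filter$type)) filter$type <- "high"
  }
  structure(list(mean = mean, sd = sd, dc_offset = dc_offset,
                 filter = filter, seed = seed),
            class = "noise_spec")
}

#' Specification of the electrode-like sampling of network units
#'
#' The simulated iEEG signal is formed by summing the activity of a random
#' fraction `alpha` of the network units. Two disjoint samples can be
#' drawn, mirroring the empirical convention in which auto-spectra come
#' from one set of recording sites and cross-spectra from pairs across two
#' sets.
#'
#' @param alpha Sampling fraction in (0, 1]; each sample contains
#'   `max(1, round(alpha * N))` distinct units.
#' @param n_samples Number of disjoint samples to draw (1 or 2).
#' @param seed Optional integer seed for the unit draw.
#' @return An object of class `proxy_spec`.
#' @export
proxy_spec <- function(alpha = 0.01, n_samples = 2, seed = NULL) {
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("proxy_spec: alpha must lie in (0, 1]")
  if (!n_samples %in% c(1L, 2L))
    stop("proxy_spec: n_samples must be 1 or 2")
  structure(list(alpha = alpha, n_samples = as.integer(n_samples), seed = seed),
            class = "proxy_spec")
}

#' Block structure of a rest/recall style simulation protocol
#'
#' @param block_length Length of each condition block, seconds.
#' @param discard Initial stabilization period discarded from each block,
#'   seconds; must be shorter than the block.
#' @param conditions Named list of conditions; each element is either a
#'   [noise_spec()] (conditions differing by the drive, e.g. an `I_add`
#'   shift) or a list `list(gain_mult = )` multiplying the network gain.
#' @return An object of class `block_protocol`.
#' @export
block_protocol <- function(block_length = 1800, discard = 600,
                           conditions = list(
                             rest = noise_spec(dc_offset = 0),
                             recall = noise_spec(dc_offset = 12.5))) {
  if (discard >= block_length)
    stop("block_protocol: discard must be shorter than block_length")
  if (length(conditions) < 1 || is.null(names(conditions)))
    stop("block_protocol: conditions must be a named, nonempty list")
  structure(list(block_length = block_length, discard = discard,
                 conditions = conditions),
            class = "block_protocol")
}

#' Read and write simulation configurations
#'
#' Round-trips the parameter objects through a YAML file with sections
#' `network`, `noise`, `protocol` and `bands`, so that runs are fully
#' described by a plain-text config.
#'
#' @param path Path of the YAML file.
#' @param network A [network_params()] object.
#' @param noise A [noise_spec()] object.
#' @param proxy A [proxy_spec()] object.
#' @param bands Optional named list of `c(lo, hi)` frequency bands, Hz.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   a list with elements `network`, `noise`, `proxy` and `bands`.
#' @export
write_config <- function(path, network = network_params(),
                         noise = noise_spec(), proxy = proxy_spec(),
                         bands = list(slow = c(0.01, 0.1), fast = c(1, 10))) {
  cfg <- list(network = unclass(network), noise = unclass(noise),
              proxy = unclass(proxy), bands = lapply(bands, as.numeric))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  net <- cfg$network
  noi <- cfg$noise
  prx <- cfg$proxy
  list(network = network_params(net$n_units, net$sparseness, net$conn_mean,
                                net$conn_sd, net$gain, net$tau, net$dt,
                                seed = net$seed),
       noise = noise_spec(noi$mean, noi$sd, noi$dc_offset, noi$filter,
                          seed = noi$seed),
       proxy = proxy_spec(prx$alpha, prx$n_samples, seed = prx$seed),
       bands = lapply(cfg$bands, as.numeric))
}
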