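#' Control parameter of the recurrent network
#'
#' Proximity to the critical point is governed by the dimensionless
#' product `G = gain * sparseness * conn_mean`. Random-matrix analysis of
#' the linearized dynamics shows that the dominant eigenvalue of the
#' Jacobian is `(-1 + G) / tau`, so the network loses stability exactly at
#' `G = 1`.
#'
#' @param gain Slope of the f-I curve, Hz/pA.
#' @param sparseness Connection probability.
#' @param conn_mean Mean nonzero connection strength (before `1/N`
#'   normalization), pA/Hz.
#' @return The dimensionless control parameter G.
#' @examples
#' control_parameter(0.1, 0.2, 49.881)  # ~ 1, the critical point
#' @export
control_parameter <- function(gain, sparseness, conn_mean) {
  v <- c(gain, sparseness, conn_mean)
  if (!all(is.finite(v))) stop("control_parameter: arguments must be finite")
  if (any(v < 0)) stop("control_parameter: arguments must be nonnegative")
  gain * sparseness * conn_mean
}

#' Gain required to reach a target control parameter
#'
#' Inverse of [control_parameter()] in its first argument:
#' `gamma = target_G / (sparseness * conn_mean)`.
#'
#' @param target_G Desired control parameter (nonnegative).
#' @param sparseness Connection probability.
#' @param conn_mean Mean nonzero connection strength, pA/Hz.
#' @return The gain `gamma` such that the forward map returns `target_G`.
#' @export
gamma_for_G <- function(target_G, sparseness, conn_mean) {
  if (!all(is.finite(c(target_G, sparseness, conn_mean))))
    stop("gamma_for_G: arguments must be finite")
  if (target_G < 0) stop("gamma_for_G: target_G must be nonnegative")
  denom <- sparseness * conn_mean
  if (denom <= 0)
    stop("gamma_for_G: sparseness * conn_mean must be positive")
  target_G / denom
}

#' Realize a sparse random weight matrix
#'
#' Each of the `N^2` entries is nonzero with probability `sparseness`;
#' nonzero entries are drawn from `Normal(conn_mean / N, (conn_sd / N)^2)`.
#' The `1/N` normalization of the mean makes the isolated real eigenvalue
#' of `gain * W` concentrate at `G = gain * sparseness * conn_mean`, so the
#' printed criticality condition `G = 1` holds independently of network
#' size. Self-connections are treated like any other entry.
#'
#' @param params A [network_params()] object; its `seed`, when set, makes
#'   the realization reproducible.
#' @return An object of class `weight_matrix` with elements `weights`
#'   (N x N), `params`, and `realized_sparseness`.
#' @export
build_weights <- function(params) {
  stopifnot(inherits(params, "network_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_units
  mask <- stats::rbinom(n * n, 1L, params$sparseness)
  vals <- stats::rnorm(n * n, mean = params$conn_mean / n,
                       sd = params$conn_sd / n)
  w <- matrix(mask * vals, n, n)
  structure(list(weights = w, params = params,
                 realized_sparseness = mean(mask)),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("Weight matrix: %d x %d, realized sparseness %.4f (target %.4f)\n",
              nrow(x$weights), ncol(x$weights), x$realized_sparseness,
              x$params$sparseness))
  invisible(x)
}

#' Linearize the network around its operating point
#'
#' Computes the full eigen-spectrum of `gain * W`. For sparse random
#' matrices built by [build_weights()] this spectrum is a bulk of complex
#' eigenvalues plus a single isolated real eigenvalue on the uniform mode;
#' its real part is the effective gain `G_eff` of the realization. The
#' dominant Jacobian eigenvalue is `(G_eff - 1) / tau`, negative iff the
#' realization is subcritical, and the relaxation time of the uniform mode
#' is `tau / (1 - G_eff)`, which diverges as criticality is approached
#' (critical slowing down).
#'
#' @param W A `weight_matrix` or a plain square numeric matrix.
#' @param gain Gain `gamma`; defaults to the gain stored in `W`'s params.
#' @param tau Time constant in seconds; defaults likewise.
#' @return An object of class `linearization_report` with fields
#'   `eigenvalues`, `dominant_real`, `effective_gain`,
#'   `jacobian_dominant` (1/s) and `predicted_timescale` (s; `Inf` when
#'   `G_eff >= 1`).
#' @export
linearize <- function(W, gain = NULL, tau = NULL) {
  if (inherits(W, "weight_matrix")) {
    if (is.null(gain)) gain <- W$params$gain
    if (is.null(tau)) tau <- W$params$tau
    W <- W$weights
  }
  if (is.null(gain) || is.null(tau))
    stop("linearize: gain and tau are required for a plain matrix")
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop("linearize: W must be square")
  ev <- tryCatch(eigen(gain * W, only.values = TRUE)$values,
                 error = function(e)
                   stop(sprintf("linearize: eigen-decomposition failed (%s); N = %d, any NA = %s",
                                conditionMessage(e), nrow(W),
                                anyNA(W))))
  g_eff <- max(Re(ev))
  structure(list(eigenvalues = ev,
                 dominant_real = g_eff,
                 effective_gain = g_eff,
                 jacobian_dominant = (g_eff - 1) / tau,
                 predicted_timescale = if (g_eff < 1) tau / (1 - g_eff) else Inf),
            class = "linearization_report")
}

#' @export
print.linearization_report <- function(x, ...) {
  cat(sprintf("Linearization: G_eff = %.4f, dominant Jacobian eigenvalue = %.3f 1/s\n",
              x$effective_gain, x$jacobian_dominant))
  cat(sprintf("  predicted uniform-mode timescale = %s\n",
              if (is.finite(x$predicted_timescale))
                sprintf("%.3f s", x$predicted_timescale) else "Inf (supercritical)"))
  invisible(x)
}
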