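# Small network configurations used across tests. Durations and sizes are
# deliberately modest: the statistical claims under test concern means and
# band powers, which stabilize quickly at these scales.

tiny_params <- function(n = 40, g = 0.9, seed = 1, tau = 0.020) {
  network_params(n_units = n, sparseness = 0.2, conn_mean = 49.881,
                 conn_sd = 4.988,
                 gain = if (g > 0) gamma_for_G(g, 0.2, 49.881) else 0.1,
                 tau = tau, seed = seed)
}

# brute-force eigenvalues via the characteristic polynomial
# (Faddeev-LeVerrier coefficients + polyroot), independent of eigen()
charpoly_eigen <- function(m) {
  n <- nrow(m)
  cs <- numeric(n + 1)
  cs[1] <- 1
  mk <- diag(n)
  for (k in 1:n) {
    mk <- m %*% mk
    cs[k + 1] <- -sum(diag(mk)) / k
    mk <- mk + cs[k + 1] * diag(n)
  }
  # polyroot takes ascending coefficients of c0 + c1 x + ...
  polyroot(rev(cs))
}

# exact two-sided signed-rank p by enumeration of all sign assignments
brute_signrank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% rk)
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# textbook Benjamini-Hochberg step-up
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# hand-built spectrum_estimate for fit tests
synthetic_spectrum <- function(freqs, power, fs = NA_real_) {
  structure(list(freqs = freqs, power = power, fs = fs,
                 segment_length = NA, overlap = NA, window = "synthetic",
                 scale_k = 1, n_segments = NA),
            class = "spectrum_estimate")
}
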