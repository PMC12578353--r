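#include <RcppArmadillo.h>
#include <cstdint>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// xoshiro256++ seeded through splitmix64: fast, and fully specified here
// so a given seed yields the same stream on every platform.
struct Xoshiro256pp {
  std::uint64_t s[4];
  explicit Xoshiro256pp(std::uint64_t seed) {
    for (int i = 0; i < 4; ++i) {
      seed += 0x9E3779B97f4A7C15ULL;
      std::uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static std::uint64_t rotl(std::uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  std::uint64_t next() {
    const std::uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const std::uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double uniform() {  // 53-bit uniform in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  std::int32_t int32() { return (std::int32_t)(next() >> 32); }
};

// Marsaglia-Tsang 128-layer ziggurat for the standard normal.
struct ZigguratNormal {
  Xoshiro256pp rng;
  std::uint32_t kn[128];
  double wn[128], fn[128];
  explicit ZigguratNormal(std::uint64_t seed) : rng(seed) {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn, vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (std::uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (std::uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
  double operator()() {
    for (;;) {
      std::int32_t hz = rng.int32();
      std::uint32_t iz = hz & 127;
      if ((std::uint32_t)std::abs(hz) < kn[iz]) return hz * wn[iz];
      const double r = 3.442619855899;
      double x = hz * wn[iz];
      if (iz == 0) {  // tail
        double y;
        do {
          x = -std::log(rng.uniform()) / r;
          y = -std::log(rng.uniform());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -r - x;
      }
      if (fn[iz] + rng.uniform() * (fn[iz - 1] - fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};

// Forward-Euler integration of the rectified-linear rate network
//
//   tau * dr/dt = -r + gain * [ W r + I_ext(t) ]_+
//
// `Wt` is the TRANSPOSE of the weight matrix in CSC storage, i.e. W in
// row-major (CSR) form, so the matvec is a cache-friendly gather.
// The external input is either white noise generated in-loop (one
// independent draw per unit per step, held constant within the step) or a
// pre-computed n_units x n_steps matrix for spectrally shaped drives.
// State is decimated by `keep_every` for output after a causal anti-alias
// filter (`sos_b`/`sos_a`: biquad cascade rows (b0,b1,b2) / (1,a1,a2),
// designed in R; empty matrices disable filtering). Any rate exceeding
// `overflow_guard` aborts: a bounded near-critical simulation never
// approaches the guard, so hitting it flags a supercritical realization.
// [[Rcpp::export]]
arma::mat sim_euler_cpp(const arma::sp_mat& Wt,
                        double gain,
                        double tau,
                        double dt,
                        int n_steps,
                        int keep_every,
                        const arma::vec& init,
                        bool noise_in_loop,
                        double noise_mean,
                        double noise_sd,
                        double noise_seed,
                        const arma::mat& drive,
                        const arma::mat& noise_sos_b,
                        const arma::mat& noise_sos_a,
                        const arma::mat& sos_b,
                        const arma::mat& sos_a,
                        double overflow_guard) {
  const arma::uword n = Wt.n_rows;
  if (Wt.n_cols != n) stop("weight matrix must be square");
  if (init.n_elem != n) stop("initial state length does not match network size");
  if (!noise_in_loop && (drive.n_rows != n || drive.n_cols < (arma::uword)n_steps))
    stop("drive matrix must be n_units x n_steps");

  const arma::uword* rowp = Wt.col_ptrs;   // row pointers of W
  const arma::uword* colx = Wt.row_indices;  // column indices of W
  const double* vals = Wt.values;

  ZigguratNormal rng((std::uint64_t)noise_seed);

  const int n_keep = n_steps / keep_every;
  const int n_sec = sos_b.n_rows;
  const int n_nsec = noise_sos_b.n_rows;
  arma::mat out(n, n_keep);
  std::vector<double> r(init.begin(), init.end());
  std::vector<double> input(n);
  std::vector<double> y(n);
  // transposed direct-form-II states, per section per unit
  std::vector<double> z1(n_sec * n, 0.0), z2(n_sec * n, 0.0);
  std::vector<double> nz1(n_nsec * n, 0.0), nz2(n_nsec * n, 0.0);
  const double a = dt / tau;
  const double* rp = r.data();

  int k = 0;
  for (int t = 0; t < n_steps; ++t) {
    if (noise_in_loop) {
      if (n_nsec == 0) {
        for (arma::uword i = 0; i < n; ++i)
          input[i] = noise_mean + noise_sd * rng();
      } else {
        // spectrally shaped drive: filter the zero-mean fluctuation
        // through the cascade, then restore the mean (which therefore
        // survives high-pass shaping)
        for (arma::uword i = 0; i < n; ++i)
          input[i] = noise_sd * rng();
        for (int s = 0; s < n_nsec; ++s) {
          const double b0 = noise_sos_b(s, 0), b1 = noise_sos_b(s, 1),
                       b2 = noise_sos_b(s, 2);
          const double a1 = noise_sos_a(s, 1), a2 = noise_sos_a(s, 2);
          double* z1s = nz1.data() + (std::size_t)s * n;
          double* z2s = nz2.data() + (std::size_t)s * n;
          for (arma::uword i = 0; i < n; ++i) {
            const double x = input[i];
            const double yo = b0 * x + z1s[i];
            z1s[i] = b1 * x - a1 * yo + z2s[i];
            z2s[i] = b2 * x - a2 * yo;
            input[i] = yo;
          }
        }
        for (arma::uword i = 0; i < n; ++i) input[i] += noise_mean;
      }
    } else {
      const double* dcol = drive.colptr(t);
      std::copy(dcol, dcol + n, input.begin());
    }
    double rmax = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      double acc = input[i];
      for (arma::uword idx = rowp[i]; idx < rowp[i + 1]; ++idx)
        acc += vals[idx] * rp[colx[idx]];
      if (acc < 0.0) acc = 0.0;       // rectified-linear transfer
      const double ri = r[i] + a * (gain * acc - r[i]);
      input[i] = ri;                  // reuse as next-state buffer
      if (ri > rmax) rmax = ri;
    }
    r.assign(input.begin(), input.end());
    if (rmax > overflow_guard) {
      stop("supercritical runaway: rate exceeded overflow guard at step %d "
           "(t = %.3f s); check the effective gain of this realization",
           t + 1, (t + 1) * dt);
    }
    // anti-alias filter on the state before subsampling, so the 1/f^2
    // tail above the output Nyquist is not folded back into the band
    if (n_sec > 0) {
      std::copy(r.begin(), r.end(), y.begin());
      for (int s = 0; s < n_sec; ++s) {
        const double b0 = sos_b(s, 0), b1 = sos_b(s, 1), b2 = sos_b(s, 2);
        const double a1 = sos_a(s, 1), a2 = sos_a(s, 2);
        double* z1s = z1.data() + (std::size_t)s * n;
        double* z2s = z2.data() + (std::size_t)s * n;
        for (arma::uword i = 0; i < n; ++i) {
          const double x = y[i];
          const double yo = b0 * x + z1s[i];
          z1s[i] = b1 * x - a1 * yo + z2s[i];
          z2s[i] = b2 * x - a2 * yo;
          y[i] = yo;
        }
      }
    } else {
      std::copy(r.begin(), r.end(), y.begin());
    }
    if ((t + 1) % keep_every == 0) {
      std::copy(y.begin(), y.end(), out.colptr(k));
      ++k;
    }
  }
  return out;
}
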