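#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Factor-model ROI time-series generator.
//
// x_i(t) = lam_i * g_{hemi(i)}(t) + mu * c(t) + sigma * eps_i(t)
//
// g_L, g_R, c, eps_i are independent unit-variance white Gaussian processes,
// so every pairwise covariance is available in closed form and the implied
// covariance matrix is positive semidefinite by construction.
//
// Draw order per sample t: g_L, g_R, c, then eps_1..eps_n. The generator owns
// a std::mt19937_64 stream keyed by `seed`; it does not touch R's RNG state.
//
// [[Rcpp::export(name = ".sim_factor_ts")]]
NumericMatrix sim_factor_ts(int n_samples, NumericVector lam, IntegerVector hemi,
                            double mu, double sigma, double seed) {
  const int n = lam.size();
  if (hemi.size() != n) stop("lam and hemi must have equal length");
  if (n_samples < 1) stop("n_samples must be >= 1");
  NumericMatrix X(n, n_samples);
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> N(0.0, 1.0);
  for (int t = 0; t < n_samples; ++t) {
    const double g[2] = {N(rng), N(rng)};
    const double c = mu * N(rng);
    double *col = &X(0, t);
    for (int i = 0; i < n; ++i)
      col[i] = lam[i] * g[hemi[i]] + c + sigma * N(rng);
  }
  return X;
}
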