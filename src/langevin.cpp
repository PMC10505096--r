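#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Overdamped Langevin dynamics on a periodic 1-D box with a Gaussian
// barrier U(z) = dG * exp(-z^2 / (2 w^2)) (kT units):
//   z <- z - D * U'(z) * dt + sqrt(2 D dt) * eta
// Positions are wrapped into [-L/2, L/2). Every `record` steps the wrapped
// positions are stored. Uses R's RNG so set.seed() controls the stream.
//
// z0:     initial positions (length n, already inside the box)
// Returns an (n_steps / record) x n matrix of recorded positions.
// [[Rcpp::export(name = ".langevin_kernel")]]
NumericMatrix langevin_kernel(NumericVector z0, double dG, double w,
                              double D, double L, double dt,
                              int n_steps, int record, bool wrap) {
  const int n = z0.size();
  const int n_rec = n_steps / record;
  NumericMatrix out(n_rec, n);
  std::vector<double> z(z0.begin(), z0.end());
  const double sig = std::sqrt(2.0 * D * dt);
  const double inv_w2 = 1.0 / (w * w);
  const double halfL = L / 2.0;
  int row = 0;
  RNGScope scope;
  for (int s = 1; s <= n_steps; ++s) {
    for (int j = 0; j < n; ++j) {
      double zj = z[j];
      // U'(z) = -dG * z / w^2 * exp(-z^2 / (2 w^2))
      double du = -dG * zj * inv_w2 * std::exp(-0.5 * zj * zj * inv_w2);
      zj += -D * du * dt + sig * norm_rand();
      if (wrap) {
        // wrap into [-L/2, L/2)
        zj -= L * std::floor((zj + halfL) / L);
      }
      z[j] = zj;
    }
    if (s % record == 0) {
      for (int j = 0; j < n; ++j) out(row, j) = z[j];
      ++row;
    }
  }
  return out;
}
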