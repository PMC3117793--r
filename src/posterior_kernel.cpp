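#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Posterior entropies (bits) for a batch of echoes over the joint
// (cell x strength-grid) lattice.
//
// b       : n_echo x m measurement rows (dB, floored at 0)
// mu      : m x (n_cells * n_a) floored mean vectors max(template + A, 0),
//           strength index a fastest within each cell
// half_m2 : 0.5 * mu' Sigma^-1 mu per lattice column
// w       : strength-prior weights, length n_a
// inv     : m x m inverse covariance
//
// Log-likelihoods are needed only up to per-echo constants, which cancel in
// the posterior. Per echo, y = Sigma^-1 b is computed once so each lattice
// entry costs one dot product over the non-floored elements of mu (floored
// elements are exactly zero and skipped). Per cell, the strength
// marginalization is accumulated in log space around the cell's maximum;
// entries more than `drop` nats below it are skipped (their posterior
// contribution is below exp(-drop) relative to the cell mass).
// [[Rcpp::export]]
NumericVector posterior_entropy_kernel(const NumericMatrix& b,
                                       const NumericMatrix& mu,
                                       const NumericVector& half_m2,
                                       const NumericVector& w,
                                       const NumericMatrix& inv,
                                       const double drop = 45.0) {
  const int n_echo = b.nrow();
  const int m = b.ncol();
  const int lattice = mu.ncol();
  const int n_a = w.size();
  const int n_cells = lattice / n_a;
  const double log2e = 1.4426950408889634;

  // sparse view of mu: indices of non-zero (non-floored) elements per column
  std::vector<int> nz_start(lattice + 1, 0);
  std::vector<int> nz_idx;
  std::vector<double> nz_val;
  nz_idx.reserve(static_cast<size_t>(lattice) * m / 2);
  nz_val.reserve(static_cast<size_t>(lattice) * m / 2);
  for (int ca = 0; ca < lattice; ++ca) {
    const double* col = &mu(0, ca);
    for (int j = 0; j < m; ++j) {
      if (col[j] != 0.0) {
        nz_idx.push_back(j);
        nz_val.push_back(col[j]);
      }
    }
    nz_start[ca + 1] = static_cast<int>(nz_idx.size());
  }

  NumericVector out(n_echo);
  std::vector<double> y(m), ll(n_a), log_s(n_cells);

  for (int e = 0; e < n_echo; ++e) {
    // y = Sigma^-1 b and the stability shift 0.5 * b' Sigma^-1 b
    double shift = 0.0;
    for (int i = 0; i < m; ++i) {
      double acc = 0.0;
      for (int j = 0; j < m; ++j) acc += inv(i, j) * b(e, j);
      y[i] = acc;
      shift += acc * b(e, i);
    }
    shift *= 0.5;

    double gmax = -1e300; // max of log_s over cells
    int ca = 0;
    for (int c = 0; c < n_cells; ++c) {
      double cmax = -1e300;
      for (int a = 0; a < n_a; ++a, ++ca) {
        double dot = 0.0;
        for (int k = nz_start[ca]; k < nz_start[ca + 1]; ++k) {
          dot += nz_val[k] * y[nz_idx[k]];
        }
        const double v = dot - half_m2[ca] - shift;
        ll[a] = v;
        if (v > cmax) cmax = v;
      }
      double sc = 0.0;
      const double cut = cmax - drop;
      for (int a = 0; a < n_a; ++a) {
        if (ll[a] > cut) sc += w[a] * std::exp(ll[a] - cmax);
      }
      log_s[c] = cmax + std::log(sc);
      if (log_s[c] > gmax) gmax = log_s[c];
    }

    double total = 0.0;
    for (int c = 0; c < n_cells; ++c) {
      const double d = log_s[c] - gmax;
      total += (d > -745.0) ? std::exp(d) : 0.0;
    }
    double h = 0.0;
    for (int c = 0; c < n_cells; ++c) {
      const double d = log_s[c] - gmax;
      if (d > -700.0) {
        const double p = std::exp(d) / total;
        if (p > 0.0) h -= p * std::log(p);
      }
    }
    out[e] = h * log2e;
  }
  return out;
}
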