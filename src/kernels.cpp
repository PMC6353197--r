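// Contingency-table kernels for the discrete Bayesian-network learner.
// Columns arrive as 1-based integer category codes.

#include <Rcpp.h>
using namespace Rcpp;

// mixed-radix configuration index (1-based, first column fastest)
// [[Rcpp::export]]
IntegerVector config_index_cpp(IntegerMatrix cols, IntegerVector cards) {
  const int n = cols.nrow(), p = cols.ncol();
  IntegerVector idx(n, 1);
  int stride = 1;
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) idx[i] += (cols(i, j) - 1) * stride;
    stride *= cards[j];
  }
  return idx;
}

// joint counts of (x, y, z-config); returns vector of length kx*ky*kz
// [[Rcpp::export]]
IntegerVector joint_counts_cpp(IntegerVector x, int kx, IntegerVector y,
                               int ky, IntegerVector zidx, int kz) {
  const int n = x.size();
  IntegerVector counts(kx * ky * kz, 0);
  for (int i = 0; i < n; ++i) {
    int c = (x[i] - 1) + kx * ((y[i] - 1) + ky * (zidx[i] - 1));
    counts[c]++;
  }
  return counts;
}

// G^2 statistic with per-configuration df adjustment: within each
// z-configuration with data, df += (nonzero x-marginals - 1) *
// (nonzero y-marginals - 1). Equals (kx-1)(ky-1)kz when all cells'
// marginals are populated.
// [[Rcpp::export]]
NumericVector g2_stat_cpp(IntegerVector x, int kx, IntegerVector y,
                          int ky, IntegerVector zidx, int kz) {
  const int n = x.size();
  std::vector<int> counts((size_t)kx * ky * kz, 0);
  for (int i = 0; i < n; ++i)
    counts[(size_t)(x[i] - 1) + kx * ((y[i] - 1) + (size_t)ky * (zidx[i] - 1))]++;
  double stat = 0.0;
  double df = 0.0;
  std::vector<double> rx(kx), cy(ky);
  for (int z = 0; z < kz; ++z) {
    double nz = 0.0;
    std::fill(rx.begin(), rx.end(), 0.0);
    std::fill(cy.begin(), cy.end(), 0.0);
    const size_t off = (size_t)kx * ky * z;
    for (int j = 0; j < ky; ++j)
      for (int i = 0; i < kx; ++i) {
        double o = counts[off + i + (size_t)kx * j];
        rx[i] += o; cy[j] += o; nz += o;
      }
    if (nz <= 0) continue;
    int nrx = 0, ncy = 0;
    for (int i = 0; i < kx; ++i) if (rx[i] > 0) nrx++;
    for (int j = 0; j < ky; ++j) if (cy[j] > 0) ncy++;
    df += (double)std::max(nrx - 1, 0) * std::max(ncy - 1, 0);
    for (int j = 0; j < ky; ++j)
      for (int i = 0; i < kx; ++i) {
        double o = counts[off + i + (size_t)kx * j];
        if (o > 0) stat += 2.0 * o * std::log(o * nz / (rx[i] * cy[j]));
      }
  }
  return NumericVector::create(stat, df);
}

static void g2_core(const int* x, int kx, const int* y, int ky,
                    const std::vector<int>& zidx, int kz, int n,
                    double& stat, double& df) {
  std::vector<int> counts((size_t)kx * ky * kz, 0);
  for (int i = 0; i < n; ++i)
    counts[(size_t)(x[i] - 1) + kx * ((y[i] - 1) + (size_t)ky * (zidx[i] - 1))]++;
  stat = 0.0; df = 0.0;
  std::vector<double> rx(kx), cy(ky);
  for (int z = 0; z < kz; ++z) {
    double nz = 0.0;
    std::fill(rx.begin(), rx.end(), 0.0);
    std::fill(cy.begin(), cy.end(), 0.0);
    const size_t off = (size_t)kx * ky * z;
    for (int j = 0; j < ky; ++j)
      for (int i = 0; i < kx; ++i) {
        double o = counts[off + i + (size_t)kx * j];
        rx[i] += o; cy[j] += o; nz += o;
      }
    if (nz <= 0) continue;
    int nrx = 0, ncy = 0;
    for (int i = 0; i < kx; ++i) if (rx[i] > 0) nrx++;
    for (int j = 0; j < ky; ++j) if (cy[j] > 0) ncy++;
    df += (double)std::max(nrx - 1, 0) * std::max(ncy - 1, 0);
    for (int j = 0; j < ky; ++j)
      for (int i = 0; i < kx; ++i) {
        double o = counts[off + i + (size_t)kx * j];
        if (o > 0) stat += 2.0 * o * std::log(o * nz / (rx[i] * cy[j]));
      }
  }
}

static void fill_zidx(const IntegerMatrix& mat, const IntegerVector& cards,
                      const int* zcols, int nz, std::vector<int>& zidx,
                      int& kz) {
  const int n = mat.nrow();
  zidx.assign(n, 1);
  kz = 1;
  const int* base = mat.begin();
  for (int j = 0; j < nz; ++j) {
    const int c = zcols[j] - 1;
    const int* col = base + (size_t)n * c;
    int* zi = zidx.data();
    const int stride = kz;
    for (int i = 0; i < n; ++i) zi[i] += (col[i] - 1) * stride;
    kz *= cards[c];
  }
}

// PC level step for one pair: enumerate the size-l subsets of nx
// (neighbours of x, 1-based column indices, ascending) and then of ny,
// skipping ny-subsets wholly contained in nx; return 1 as soon as a
// subset renders xi and yi independent at alpha, else 0.
// [[Rcpp::export]]
int g2_sepset_level_cpp(IntegerMatrix mat, IntegerVector cards,
                        int xi, int yi, IntegerVector nx,
                        IntegerVector ny, int l, double alpha) {
  const int n = mat.nrow();
  const int* xv = mat.begin() + (size_t)n * (xi - 1);
  const int* yv = mat.begin() + (size_t)n * (yi - 1);
  const int kx = cards[xi - 1], ky = cards[yi - 1];
  std::vector<int> zidx;
  double stat, df;
  std::vector<bool> in_nx((size_t)mat.ncol() + 1, false);
  for (int i = 0; i < nx.size(); ++i) in_nx[nx[i]] = true;
  std::vector<int> zc(l);
  int kz;
  if (l == 0) {
    fill_zidx(mat, cards, zc.data(), 0, zidx, kz);
    g2_core(xv, kx, yv, ky, zidx, kz, n, stat, df);
    if (df > 0 && R::pchisq(stat, df, 0, 0) > alpha) return 1;
    return 0;
  }
  for (int side = 0; side < 2; ++side) {
    const IntegerVector& nb = (side == 0) ? nx : ny;
    const int m = nb.size();
    if (m < l) continue;
    std::vector<int> c(l);
    for (int j = 0; j < l; ++j) c[j] = j;
    while (true) {
      bool skip = false;
      if (side == 1) {
        skip = true;
        for (int j = 0; j < l; ++j)
          if (!in_nx[nb[c[j]]]) { skip = false; break; }
      }
      if (!skip) {
        for (int j = 0; j < l; ++j) zc[j] = nb[c[j]];
        fill_zidx(mat, cards, zc.data(), l, zidx, kz);
        g2_core(xv, kx, yv, ky, zidx, kz, n, stat, df);
        if (df > 0 && R::pchisq(stat, df, 0, 0) > alpha) return 1;
      }
      // next combination
      int j = l - 1;
      while (j >= 0 && c[j] == m - l + j) --j;
      if (j < 0) break;
      ++c[j];
      for (int t = j + 1; t < l; ++t) c[t] = c[t - 1] + 1;
    }
  }
  return 0;
}

// Local BIC of column xi given parent columns (1-based indices):
// multinomial log-likelihood minus log(n)/2 * (kx - 1) * prod(parent
// cardinalities).
// [[Rcpp::export]]
double local_bic_cpp(IntegerMatrix mat, IntegerVector cards, int xi,
                     IntegerVector pcols) {
  const int n = mat.nrow();
  std::vector<int> zidx; int kz;
  fill_zidx(mat, cards, pcols.begin(), pcols.size(), zidx, kz);
  const int kx = cards[xi - 1];
  std::vector<double> counts((size_t)kx * kz, 0.0), ptot(kz, 0.0);
  for (int i = 0; i < n; ++i) {
    counts[(size_t)(mat(i, xi - 1) - 1) + (size_t)kx * (zidx[i] - 1)] += 1.0;
    ptot[zidx[i] - 1] += 1.0;
  }
  double ll = 0.0;
  for (int c = 0; c < kz; ++c) {
    if (ptot[c] <= 0) continue;
    for (int i = 0; i < kx; ++i) {
      double o = counts[(size_t)i + (size_t)kx * c];
      if (o > 0) ll += o * std::log(o / ptot[c]);
    }
  }
  return ll - std::log((double)n) / 2.0 * (kx - 1) * (double)kz;
}

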