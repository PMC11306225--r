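#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Chebyshev (max-norm) distance between rows i and j of X.
static inline double cheb(const NumericMatrix &X, int i, int j) {
  double d = 0.0;
  for (int c = 0; c < X.ncol(); ++c) {
    double v = std::fabs(X(i, c) - X(j, c));
    if (v > d) d = v;
  }
  return d;
}

// Kraskov-Stoegbauer-Grassberger estimator (first variant) of the mutual
// information between a continuous multivariate X and a continuous scalar
// y, in nats. Assumes ties have been broken by jitter upstream.
// [[Rcpp::export]]
double cpp_ksg_mi(NumericMatrix X, NumericVector y, int k) {
  const int n = X.nrow();
  if (n <= k + 1) return NA_REAL;
  std::vector<double> dz(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (j == i) { dz[j] = R_PosInf; continue; }
      double dx = cheb(X, i, j);
      double dy = std::fabs(y[i] - y[j]);
      dz[j] = dx > dy ? dx : dy;
    }
    std::vector<double> tmp(dz);
    std::nth_element(tmp.begin(), tmp.begin() + (k - 1), tmp.end());
    double eps = tmp[k - 1];
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (cheb(X, i, j) < eps) ++nx;
      if (std::fabs(y[i] - y[j]) < eps) ++ny;
    }
    acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
  }
  return R::digamma((double)k) + R::digamma((double)n) - acc / n;
}

// Nearest-neighbour mutual information between continuous X and a discrete
// class label, in nats: for each point, the k-th neighbour distance within
// its own class defines a radius whose occupancy in the full sample is
// compared against the class size.
// [[Rcpp::export]]
double cpp_mixed_mi(NumericMatrix X, IntegerVector cls, int k) {
  const int n = X.nrow();
  std::vector<int> count;
  std::vector<int> cls0(n);
  {
    std::vector<int> uniq;
    for (int i = 0; i < n; ++i) {
      int c = cls[i];
      int idx = -1;
      for (size_t u = 0; u < uniq.size(); ++u) if (uniq[u] == c) { idx = (int)u; break; }
      if (idx < 0) { uniq.push_back(c); count.push_back(0); idx = (int)uniq.size() - 1; }
      cls0[i] = idx;
      count[idx]++;
    }
  }
  double acc = 0.0;
  int used = 0;
  std::vector<double> dsame;
  for (int i = 0; i < n; ++i) {
    int nc = count[cls0[i]];
    if (nc < 2) continue;
    int ki = std::min(k, nc - 1);
    dsame.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i || cls0[j] != cls0[i]) continue;
      dsame.push_back(cheb(X, i, j));
    }
    std::nth_element(dsame.begin(), dsame.begin() + (ki - 1), dsame.end());
    double di = dsame[ki - 1];
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (cheb(X, i, j) <= di) ++m;
    }
    acc += R::digamma((double)ki) - R::digamma((double)nc) - R::digamma((double)m);
    ++used;
  }
  if (used == 0) return 0.0;
  return R::digamma((double)n) + acc / used;
}
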