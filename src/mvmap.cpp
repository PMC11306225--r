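#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Circular cross-correlation alignment followed by Euclidean distance,
// matching the R reference implementation align()/pair_distance(): the lag
// (searched in the order 0, +1, -1, +2, -2, ...) maximizes the dot product
// of the mean-removed vectors, strictly-greater updates breaking ties
// toward the smallest |lag|.

static double aligned_distance(const double *xi, const double *xj, int L,
                               int max_lag, int *best_lag_out) {
  std::vector<double> a(L), b(L);
  double ma = 0.0, mb = 0.0;
  for (int t = 0; t < L; ++t) { ma += xi[t]; mb += xj[t]; }
  ma /= L; mb /= L;
  for (int t = 0; t < L; ++t) { a[t] = xi[t] - ma; b[t] = xj[t] - mb; }

  int best_lag = 0;
  double best = R_NegInf;
  bool degenerate = true;
  for (int t = 0; t < L; ++t) if (a[t] != 0.0 || b[t] != 0.0) { degenerate = false; break; }
  if (!degenerate) {
    for (int m = 0; m <= max_lag; ++m) {
      for (int sgn = 0; sgn < (m == 0 ? 1 : 2); ++sgn) {
        int lag = (sgn == 0) ? m : -m;
        double s = 0.0;
        for (int t = 0; t < L; ++t) {
          int idx = t - lag;
          idx %= L;
          if (idx < 0) idx += L;
          s += a[t] * b[idx];
        }
        if (s > best) { best = s; best_lag = lag; }
      }
    }
  }
  double d2 = 0.0;
  for (int t = 0; t < L; ++t) {
    int idx = t - best_lag;
    idx %= L;
    if (idx < 0) idx += L;
    double diff = xi[t] - xj[idx];
    d2 += diff * diff;
  }
  *best_lag_out = best_lag;
  return std::sqrt(d2);
}

// Exhaustive O(n^2) scan for multi-valued mappings: pairs in scope whose
// labels differ by >= out_th and whose aligned Euclidean distance is
// <= in_th. The optional pre-screen skips pairs whose unaligned distance
// lower bound already exceeds in_th; it cannot change the result set. Two
// bounds are used, both valid under any circular shift: the L2 distance of
// the magnitude spectra (Parseval plus the per-frequency triangle
// inequality; `Spec` holds |FFT(row)| / sqrt(L)), and the L2 distance of
// the sorted sample values (rearrangement inequality).
// [[Rcpp::export]]
List cpp_find_matches(NumericMatrix W, NumericMatrix Spec,
                      NumericVector y, IntegerVector pid,
                      bool intra, double in_th, double out_th, int max_lag,
                      bool prescreen) {
  const int n = W.nrow(), L = W.ncol();
  // row-major copies: raw values and sorted values
  std::vector<double> V((size_t)n * L), S((size_t)n * L);
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < L; ++t) V[(size_t)i * L + t] = W(i, t);
    std::copy(V.begin() + (size_t)i * L, V.begin() + (size_t)(i + 1) * L,
              S.begin() + (size_t)i * L);
    std::sort(S.begin() + (size_t)i * L, S.begin() + (size_t)(i + 1) * L);
  }
  LogicalVector matched(n, false);
  std::vector<int> pi, pj, plag;
  std::vector<double> pdist, pdy;
  // lower bounds are compared with a small relative margin so that
  // floating-point accumulation can never prune an exact-boundary pair
  const double in_th2 = in_th * in_th * (1.0 + 1e-9) + 1e-12;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      bool same = pid[i] == pid[j];
      if (intra != same) continue;
      double dy = std::fabs(y[i] - y[j]);
      if (dy < out_th) continue;
      if (prescreen) {
        double lb2 = 0.0;
        for (int t = 0; t < Spec.ncol(); ++t) {
          double d = Spec(i, t) - Spec(j, t);
          lb2 += d * d;
          if (lb2 > in_th2) break;
        }
        if (lb2 > in_th2) continue;
        lb2 = 0.0;
        const double *si = &S[(size_t)i * L], *sj = &S[(size_t)j * L];
        for (int t = 0; t < L; ++t) {
          double d = si[t] - sj[t];
          lb2 += d * d;
          if (lb2 > in_th2) break;
        }
        if (lb2 > in_th2) continue;
      }
      int lag = 0;
      double d = aligned_distance(&V[(size_t)i * L], &V[(size_t)j * L], L,
                                  max_lag, &lag);
      if (d <= in_th) {
        matched[i] = true;
        matched[j] = true;
        pi.push_back(i + 1);
        pj.push_back(j + 1);
        plag.push_back(lag);
        pdist.push_back(d);
        pdy.push_back(dy);
      }
    }
  }
  return List::create(_["matched"] = matched,
                      _["i"] = wrap(pi), _["j"] = wrap(pj),
                      _["distance"] = wrap(pdist),
                      _["dlabel"] = wrap(pdy),
                      _["lag"] = wrap(plag));
}

// Alignment of a single pair, exposed for the R wrapper.
// [[Rcpp::export]]
List cpp_align_pair(NumericVector x, NumericVector yv, int max_lag) {
  int lag = 0;
  double d = aligned_distance(REAL(x), REAL(yv), x.size(), max_lag, &lag);
  return List::create(_["lag"] = lag, _["distance"] = d);
}
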