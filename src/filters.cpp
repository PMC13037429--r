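#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// direct-form II transposed IIR, in place on one column; b and a must be
// pre-padded to length ns+1 (a[0] == 1)
static void iir_inplace(const double* b, const double* a, int ns,
                        double* x, int n, double* w) {
  for (int s = 0; s <= ns; ++s) w[s] = 0.0;  // w[ns] stays 0 (sentinel)
  for (int t = 0; t < n; ++t) {
    double xin = x[t];
    double y = b[0] * xin + w[0];
    for (int s = 0; s < ns; ++s)
      w[s] = b[s + 1] * xin - a[s + 1] * y + w[s + 1];
    x[t] = y;
  }
}

struct PaddedFilt {
  std::vector<double> b, a;
  int ns;
  PaddedFilt(NumericVector bb, NumericVector aa) {
    ns = std::max(bb.size(), aa.size()) - 1;
    b.assign(ns + 1, 0.0);
    a.assign(ns + 1, 0.0);
    for (int i = 0; i < bb.size(); ++i) b[i] = bb[i] / aa[0];
    for (int i = 0; i < aa.size(); ++i) a[i] = aa[i] / aa[0];
  }
};

// zero-phase cascade of two IIR filters with odd-reflection edge padding,
// column-wise over a time x channels matrix
// [[Rcpp::export(name = ".cpp_filtfilt2")]]
NumericMatrix cpp_filtfilt2(NumericMatrix X, NumericVector b1,
                            NumericVector a1, NumericVector b2,
                            NumericVector a2, int pad) {
  int n = X.nrow(), m = X.ncol();
  if (pad > n - 1) pad = n - 1;
  int np = n + 2 * pad;
  PaddedFilt f1(b1, a1), f2(b2, a2);
  int nsmax = std::max(f1.ns, f2.ns);
  NumericMatrix out(n, m);
  std::vector<double> y(np), w(nsmax + 1);
  for (int j = 0; j < m; ++j) {
    const double* col = &X(0, j);
    for (int t = 0; t < pad; ++t)               // odd reflection, head
      y[t] = 2.0 * col[0] - col[pad - t];
    std::copy(col, col + n, y.begin() + pad);
    for (int t = 0; t < pad; ++t)               // odd reflection, tail
      y[pad + n + t] = 2.0 * col[n - 1] - col[n - 2 - t];
    iir_inplace(f1.b.data(), f1.a.data(), f1.ns, y.data(), np, w.data());
    iir_inplace(f2.b.data(), f2.a.data(), f2.ns, y.data(), np, w.data());
    std::reverse(y.begin(), y.end());
    iir_inplace(f1.b.data(), f1.a.data(), f1.ns, y.data(), np, w.data());
    iir_inplace(f2.b.data(), f2.a.data(), f2.ns, y.data(), np, w.data());
    std::reverse(y.begin(), y.end());
    std::copy(y.begin() + pad, y.begin() + pad + n, &out(0, j));
  }
  return out;
}

static double quantile7(std::vector<double>& scratch,
                        const std::vector<double>& v, double p) {
  scratch = v;
  int n = scratch.size();
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  int hi = std::min(lo + 1, n - 1);
  std::nth_element(scratch.begin(), scratch.begin() + lo, scratch.end());
  double vlo = scratch[lo];
  double vhi = *std::min_element(scratch.begin() + hi, scratch.end());
  return vlo + (h - lo) * (vhi - vlo);
}

// periodized orthogonal DWT -> per-level IQR thresholding -> inverse,
// one column at a time; nrow(X) must be divisible by 2^depth. The
// circular wrap is only needed for the last taps, so the bulk of each
// level runs without index arithmetic.
// [[Rcpp::export(name = ".cpp_wavelet_correct")]]
NumericMatrix cpp_wavelet_correct(NumericMatrix X, NumericVector lo,
                                  NumericVector hi, int depth, double k) {
  int n = X.nrow(), m = X.ncol(), L = lo.size();
  NumericMatrix out(n, m);
  std::vector<std::vector<double> > details(depth);
  std::vector<double> approx(n), buf(n), scratch;
  const double* lp = lo.begin();
  const double* hp = hi.begin();
  for (int j = 0; j < m; ++j) {
    std::copy(&X(0, j), &X(0, j) + n, approx.begin());
    int len = n;
    for (int lev = 0; lev < depth; ++lev) {
      int K = len / 2;
      details[lev].assign(K, 0.0);
      buf.assign(K, 0.0);
      int safe = (len - L) / 2 + 1;             // no wrap for kk < safe
      if (safe < 0) safe = 0;
      for (int kk = 0; kk < safe; ++kk) {
        const double* v = &approx[2 * kk];
        double a = 0.0, d = 0.0;
        for (int tap = 0; tap < L; ++tap) {
          a += lp[tap] * v[tap];
          d += hp[tap] * v[tap];
        }
        buf[kk] = a;
        details[lev][kk] = d;
      }
      for (int kk = safe; kk < K; ++kk) {
        double a = 0.0, d = 0.0;
        for (int tap = 0; tap < L; ++tap) {
          double v = approx[(2 * kk + tap) % len];
          a += lp[tap] * v;
          d += hp[tap] * v;
        }
        buf[kk] = a;
        details[lev][kk] = d;
      }
      std::copy(buf.begin(), buf.begin() + K, approx.begin());
      len = K;
    }
    for (int lev = 0; lev < depth; ++lev) {
      std::vector<double>& D = details[lev];
      double q1 = quantile7(scratch, D, 0.25);
      double q3 = quantile7(scratch, D, 0.75);
      double iqr = q3 - q1;
      double lo_b = q1 - k * iqr, hi_b = q3 + k * iqr;
      for (size_t kk = 0; kk < D.size(); ++kk)
        if (D[kk] < lo_b || D[kk] > hi_b) D[kk] = 0.0;
    }
    for (int lev = depth - 1; lev >= 0; --lev) {
      int K = len, N2 = 2 * len;
      buf.assign(N2, 0.0);
      int safe = (N2 - L) / 2 + 1;
      if (safe < 0) safe = 0;
      for (int kk = 0; kk < safe; ++kk) {
        double a = approx[kk], d = details[lev][kk];
        double* v = &buf[2 * kk];
        for (int tap = 0; tap < L; ++tap)
          v[tap] += lp[tap] * a + hp[tap] * d;
      }
      for (int kk = safe; kk < K; ++kk) {
        double a = approx[kk], d = details[lev][kk];
        for (int tap = 0; tap < L; ++tap) {
          int row = (2 * kk + tap) % N2;
          buf[row] += lp[tap] * a + hp[tap] * d;
        }
      }
      std::copy(buf.begin(), buf.begin() + N2, approx.begin());
      len = N2;
    }
    std::copy(approx.begin(), approx.begin() + n, &out(0, j));
  }
  return out;
}
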