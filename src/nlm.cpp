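#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Symmetric (edge-including) reflection of an index into [0, n-1].
static inline int reflect_sym(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  i = ((i % period) + period) % period;
  return (i < n) ? i : (period - 1 - i);
}

// Non-local means on a 2-D plane.
//
// For every pixel m the output is sum_w(m,n) y(n) / sum_w(m,n) over the
// (2Q+1)^2 search window centred at m (truncated at the plane borders),
// with w(m,n) = exp(-d2(m,n) / (2 L lambda^2)) and d2 the sum of squared
// differences over the (2P+1)^2 patch offsets, L = (2P+1)^2.  Patches are
// extracted from a symmetric mirror padding of the plane by P; the
// self-weight falls out of the formula as exp(0) = 1.
//
// Work is organised as column tiles x window offsets x columns so the
// touched pad/num/den columns stay cache-resident across the (2Q+1)^2
// offsets; large planes are processed at full memory bandwidth.  The
// summation order (column sums, then a (2P+1)-term vertical sum) is fixed
// and matches a literal transcription of the weight formula to
// floating-point reordering accuracy.
// [[Rcpp::export]]
NumericMatrix nlm2d_cpp(const NumericMatrix& y, int P, int Q, double lambda) {
  const int R = y.nrow(), C = y.ncol();
  const int Rp = R + 2 * P, Cp = C + 2 * P;
  const double L = (double)(2 * P + 1) * (2 * P + 1);
  const double denom = 2.0 * L * lambda * lambda;
  const int W = 2 * P + 1;

  std::vector<double> pad((size_t)Rp * Cp);
  for (int c = 0; c < Cp; ++c) {
    int cs = reflect_sym(c - P, C);
    for (int r = 0; r < Rp; ++r)
      pad[(size_t)c * Rp + r] = y(reflect_sym(r - P, R), cs);
  }

  NumericMatrix num(R, C), den(R, C);
  std::vector<double> s(Rp);                // per-column patch column-sums

  const int TILE = 64;
  for (int t0 = 0; t0 < C; t0 += TILE) {
    const int t1 = std::min(C, t0 + TILE);
    for (int dc = -Q; dc <= Q; ++dc) {
      for (int dr = -Q; dr <= Q; ++dr) {
        const int r0 = std::max(0, -dr), r1 = std::min(R - 1, R - 1 - dr);
        if (r0 > r1) continue;
        const int c0 = std::max(t0, -dc), c1 = std::min(t1 - 1, C - 1 - dc);
        for (int c = c0; c <= c1; ++c) {
          // s[rr] = sum over the patch's W columns of the squared
          // difference at padded row rr, for rr spanning the patch rows
          const int rr0 = r0, rr1 = r1 + 2 * P;
          for (int rr = rr0; rr <= rr1; ++rr) s[rr] = 0.0;
          for (int k = 0; k < W; ++k) {
            const double* a = &pad[(size_t)(c + k) * Rp];
            const double* b = &pad[(size_t)(c + k + dc) * Rp + dr];
            for (int rr = rr0; rr <= rr1; ++rr) {
              double d = a[rr] - b[rr];
              s[rr] += d * d;
            }
          }
          const double* yn = &pad[(size_t)(c + dc + P) * Rp + P + dr];
          double* numc = &num[(size_t)c * R];
          double* denc = &den[(size_t)c * R];
          for (int r = r0; r <= r1; ++r) {
            double d2 = s[r];
            for (int k = 1; k < W; ++k) d2 += s[r + k];
            double w = std::exp(-d2 / denom);
            numc[r] += w * yn[r];
            denc[r] += w;
          }
        }
      }
    }
  }

  NumericMatrix out(R, C);
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < R; ++r) out(r, c) = num(r, c) / den(r, c);
  return out;
}

// 1-D non-local means (time-domain baseline), same weight formula with
// scalar sample indices, patch length 2P+1, search half-width Q.
// [[Rcpp::export]]
NumericVector nlm1d_cpp(const NumericVector& y, int P, int Q, double lambda) {
  const int N = y.size();
  const double L = 2.0 * P + 1.0;
  const double denom = 2.0 * L * lambda * lambda;

  std::vector<double> pad(N + 2 * P);
  for (int i = 0; i < N + 2 * P; ++i) pad[i] = y[reflect_sym(i - P, N)];

  NumericVector num(N), den(N);
  for (int i = 0; i < N; ++i) { num[i] = y[i]; den[i] = 1.0; }

  for (int t = 1; t <= Q; ++t) {
    for (int m = 0; m + t < N; ++m) {
      int n = m + t;
      double d2 = 0.0;
      for (int k = -P; k <= P; ++k) {
        double d = pad[m + P + k] - pad[n + P + k];
        d2 += d * d;
      }
      double w = std::exp(-d2 / denom);
      num[m] += w * y[n]; den[m] += w;
      num[n] += w * y[m]; den[n] += w;
    }
  }
  NumericVector out(N);
  for (int i = 0; i < N; ++i) out[i] = num[i] / den[i];
  return out;
}
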