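#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Running extreme over a centred window of half-width h along a contiguous
// vector (van Herk / Gil-Werman block prefix/suffix scheme), borders
// truncated.  O(1) amortised per sample.
static void running_extreme_1d(const double* x, int n, int h, bool take_max,
                               double* out) {
  int w = 2 * h + 1;
  std::vector<double> pre(n), suf(n);
  for (int i = 0; i < n; ++i)
    pre[i] = (i % w == 0) ? x[i]
             : (take_max ? std::max(pre[i - 1], x[i]) : std::min(pre[i - 1], x[i]));
  for (int i = n - 1; i >= 0; --i) {
    bool blockEnd = (i == n - 1) || ((i + 1) % w == 0);
    suf[i] = blockEnd ? x[i]
             : (take_max ? std::max(suf[i + 1], x[i]) : std::min(suf[i + 1], x[i]));
  }
  for (int i = 0; i < n; ++i) {
    int lo = i - h, hi = i + h;
    if (lo < 0) lo = 0;
    if (hi > n - 1) hi = n - 1;
    double v;
    if (hi / w == lo / w) {
      if (lo % w == 0 && (hi == n - 1 || hi % w == w - 1)) {
        v = suf[lo];                          // window is exactly one block
      } else {                                // truncated border window
        v = x[lo];
        for (int j = lo + 1; j <= hi; ++j)
          v = take_max ? std::max(v, x[j]) : std::min(v, x[j]);
      }
    } else {
      v = take_max ? std::max(suf[lo], pre[hi]) : std::min(suf[lo], pre[hi]);
    }
    out[i] = v;
  }
}

// Separable moving max/min over a (2h+1)x(2h+1) window, truncated at
// borders.  The horizontal pass keeps column-major access by building the
// block prefix/suffix planes with a one-column rolling state.
// [[Rcpp::export]]
NumericMatrix moving_extreme_cpp(const NumericMatrix& m, int h, bool take_max) {
  const int R = m.nrow(), C = m.ncol();
  const int w = 2 * h + 1;
  NumericMatrix tmp(R, C), out(R, C);
  {
    std::vector<double> res(R);
    for (int c = 0; c < C; ++c) {
      running_extreme_1d(&m[(size_t)c * R], R, h, take_max, res.data());
      std::copy(res.begin(), res.end(), &tmp[(size_t)c * R]);
    }
  }
  // horizontal pass on tmp
  std::vector<double> pre((size_t)R * C), suf((size_t)R * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &tmp[(size_t)c * R];
    double* pc = &pre[(size_t)c * R];
    if (c % w == 0) std::copy(xc, xc + R, pc);
    else {
      const double* pm = &pre[(size_t)(c - 1) * R];
      for (int r = 0; r < R; ++r)
        pc[r] = take_max ? std::max(pm[r], xc[r]) : std::min(pm[r], xc[r]);
    }
  }
  for (int c = C - 1; c >= 0; --c) {
    const double* xc = &tmp[(size_t)c * R];
    double* sc = &suf[(size_t)c * R];
    if (c == C - 1 || (c + 1) % w == 0) std::copy(xc, xc + R, sc);
    else {
      const double* sp = &suf[(size_t)(c + 1) * R];
      for (int r = 0; r < R; ++r)
        sc[r] = take_max ? std::max(sp[r], xc[r]) : std::min(sp[r], xc[r]);
    }
  }
  for (int c = 0; c < C; ++c) {
    int lo = std::max(0, c - h), hi = std::min(C - 1, c + h);
    double* oc = &out[(size_t)c * R];
    if (hi / w == lo / w) {
      if (lo % w == 0 && (hi == C - 1 || hi % w == w - 1)) {
        const double* sc = &suf[(size_t)lo * R];
        std::copy(sc, sc + R, oc);
      } else {
        const double* x0 = &tmp[(size_t)lo * R];
        std::copy(x0, x0 + R, oc);
        for (int cc = lo + 1; cc <= hi; ++cc) {
          const double* xc = &tmp[(size_t)cc * R];
          for (int r = 0; r < R; ++r)
            oc[r] = take_max ? std::max(oc[r], xc[r]) : std::min(oc[r], xc[r]);
        }
      }
    } else {
      const double* sc = &suf[(size_t)lo * R];
      const double* pc = &pre[(size_t)hi * R];
      for (int r = 0; r < R; ++r)
        oc[r] = take_max ? std::max(sc[r], pc[r]) : std::min(sc[r], pc[r]);
    }
  }
  return out;
}

// Separable box mean over a (2h+1)x(2h+1) window; border windows truncated
// and normalised by the actual count.  Vertical pass uses per-column
// cumulative sums; horizontal pass keeps a rolling accumulator column so
// all access stays column-major.
// [[Rcpp::export]]
NumericMatrix box_mean_cpp(const NumericMatrix& m, int h) {
  const int R = m.nrow(), C = m.ncol();
  NumericMatrix tmp(R, C), out(R, C);
  {
    std::vector<double> cum(R + 1);
    for (int c = 0; c < C; ++c) {
      const double* xc = &m[(size_t)c * R];
      cum[0] = 0.0;
      for (int r = 0; r < R; ++r) cum[r + 1] = cum[r] + xc[r];
      double* tc = &tmp[(size_t)c * R];
      for (int r = 0; r < R; ++r) {
        int lo = std::max(0, r - h), hi = std::min(R - 1, r + h);
        tc[r] = (cum[hi + 1] - cum[lo]) / (hi - lo + 1);
      }
    }
  }
  std::vector<double> acc(R, 0.0);
  int cnt = 0;
  for (int c = 0; c <= std::min(C - 1, h); ++c) {     // prime [0, h]
    const double* tc = &tmp[(size_t)c * R];
    for (int r = 0; r < R; ++r) acc[r] += tc[r];
    ++cnt;
  }
  for (int c = 0; c < C; ++c) {
    double* oc = &out[(size_t)c * R];
    for (int r = 0; r < R; ++r) oc[r] = acc[r] / cnt;
    int add = c + h + 1, drop = c - h;
    if (add < C) {
      const double* tc = &tmp[(size_t)add * R];
      for (int r = 0; r < R; ++r) acc[r] += tc[r];
      ++cnt;
    }
    if (drop >= 0) {
      const double* tc = &tmp[(size_t)drop * R];
      for (int r = 0; r < R; ++r) acc[r] -= tc[r];
      --cnt;
    }
  }
  return out;
}

// Classify every pixel against its neighbours (4- or 8-connectivity,
// borders use existing neighbours only):
//   1  strictly greater than all neighbours (local maximum)
//  -1  strictly smaller than all neighbours (local minimum)
//   2  equal to at least one neighbour (candidate plateau member)
//   0  neither
// [[Rcpp::export]]
IntegerMatrix extrema_scan_cpp(const NumericMatrix& m, int connectivity) {
  const int R = m.nrow(), C = m.ncol();
  IntegerMatrix code(R, C);
  const bool conn8 = (connectivity == 8);
  for (int c = 0; c < C; ++c) {
    const double* cur = &m[(size_t)c * R];
    const double* lef = (c > 0) ? &m[(size_t)(c - 1) * R] : nullptr;
    const double* rig = (c < C - 1) ? &m[(size_t)(c + 1) * R] : nullptr;
    int* oc = &code[(size_t)c * R];
    for (int r = 0; r < R; ++r) {
      const double v = cur[r];
      bool anyGT = false, anyLT = false, anyEQ = false;
      auto look = [&](double u) {
        if (u == v) anyEQ = true;
        else if (u > v) anyGT = true;
        else anyLT = true;
      };
      if (r > 0) look(cur[r - 1]);
      if (r < R - 1) look(cur[r + 1]);
      if (lef) {
        look(lef[r]);
        if (conn8 && r > 0) look(lef[r - 1]);
        if (conn8 && r < R - 1) look(lef[r + 1]);
      }
      if (rig) {
        look(rig[r]);
        if (conn8 && r > 0) look(rig[r - 1]);
        if (conn8 && r < R - 1) look(rig[r + 1]);
      }
      if (anyEQ) oc[r] = 2;
      else if (!anyGT) oc[r] = 1;
      else if (!anyLT) oc[r] = -1;
      else oc[r] = 0;
    }
  }
  return code;
}
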