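#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Median filter with edge replication. Mask dimensions must be odd.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix img, int mr, int mc) {
  int M = img.nrow(), N = img.ncol();
  int hr = mr / 2, hc = mc / 2;
  NumericMatrix out(M, N);
  std::vector<double> buf((size_t)mr * mc);
  for (int n = 0; n < N; ++n) {
    for (int m = 0; m < M; ++m) {
      size_t k = 0;
      for (int dc = -hc; dc <= hc; ++dc) {
        int nn = n + dc;
        if (nn < 0) nn = 0; else if (nn >= N) nn = N - 1;
        for (int dr = -hr; dr <= hr; ++dr) {
          int mm = m + dr;
          if (mm < 0) mm = 0; else if (mm >= M) mm = M - 1;
          buf[k++] = img(mm, nn);
        }
      }
      // lower median for even window sizes keeps an existing grey level
      size_t mid = (buf.size() - 1) / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      out(m, n) = buf[mid];
    }
  }
  return out;
}

// Neighborhood extreme (min or max) over an explicit offset set.
// offsets: k x 2 matrix of (dm, dn), applied as (m + dm, n + dn) when
// forward, (m - dm, n - dn) otherwise. Out-of-image members are ignored
// (shrinking window); a pixel whose whole window falls outside keeps its
// own value (cannot happen when (0,0) is a member).
// [[Rcpp::export]]
NumericMatrix cpp_neigh_extreme(NumericMatrix img, IntegerMatrix offsets,
                                bool take_max, bool forward) {
  int M = img.nrow(), N = img.ncol(), K = offsets.nrow();
  int sgn = forward ? 1 : -1;
  NumericMatrix out(M, N);
  const double *src = img.begin();
  double *dst = out.begin();
  std::vector<int> dm(K), dn(K), lin(K);
  int dm_lo = 0, dm_hi = 0, dn_lo = 0, dn_hi = 0;
  for (int k = 0; k < K; ++k) {
    dm[k] = sgn * offsets(k, 0);
    dn[k] = sgn * offsets(k, 1);
    lin[k] = dm[k] + dn[k] * M;
    dm_lo = std::min(dm_lo, dm[k]); dm_hi = std::max(dm_hi, dm[k]);
    dn_lo = std::min(dn_lo, dn[k]); dn_hi = std::max(dn_hi, dn[k]);
  }
  for (int n = 0; n < N; ++n) {
    bool col_in = (n + dn_lo >= 0) && (n + dn_hi < N);
    int m_in_lo = -dm_lo, m_in_hi = M - dm_hi;  // [lo, hi) fully inside
    for (int m = 0; m < M; ++m) {
      bool seen = false;
      double best = 0.0;
      if (col_in && m >= m_in_lo && m < m_in_hi) {
        const double *p = src + (size_t)n * M + m;
        best = p[lin[0]]; seen = true;
        if (take_max) {
          for (int k = 1; k < K; ++k) { double v = p[lin[k]]; if (v > best) best = v; }
        } else {
          for (int k = 1; k < K; ++k) { double v = p[lin[k]]; if (v < best) best = v; }
        }
      } else {
        for (int k = 0; k < K; ++k) {
          int mm = m + dm[k], nn = n + dn[k];
          if (mm < 0 || mm >= M || nn < 0 || nn >= N) continue;
          double v = src[(size_t)nn * M + mm];
          if (!seen || (take_max ? v > best : v < best)) { best = v; seen = true; }
        }
      }
      dst[(size_t)n * M + m] = seen ? best : src[(size_t)n * M + m];
    }
  }
  return out;
}

// Neighborhood mean over an explicit offset set, same border convention.
// [[Rcpp::export]]
NumericMatrix cpp_neigh_mean(NumericMatrix img, IntegerMatrix offsets,
                             bool forward) {
  int M = img.nrow(), N = img.ncol(), K = offsets.nrow();
  int sgn = forward ? 1 : -1;
  NumericMatrix out(M, N);
  const double *src = img.begin();
  double *dst = out.begin();
  std::vector<int> dm(K), dn(K), lin(K);
  int dm_lo = 0, dm_hi = 0, dn_lo = 0, dn_hi = 0;
  for (int k = 0; k < K; ++k) {
    dm[k] = sgn * offsets(k, 0);
    dn[k] = sgn * offsets(k, 1);
    lin[k] = dm[k] + dn[k] * M;
    dm_lo = std::min(dm_lo, dm[k]); dm_hi = std::max(dm_hi, dm[k]);
    dn_lo = std::min(dn_lo, dn[k]); dn_hi = std::max(dn_hi, dn[k]);
  }
  for (int n = 0; n < N; ++n) {
    bool col_in = (n + dn_lo >= 0) && (n + dn_hi < N);
    int m_in_lo = -dm_lo, m_in_hi = M - dm_hi;
    for (int m = 0; m < M; ++m) {
      double s = 0.0; int cnt = 0;
      if (col_in && m >= m_in_lo && m < m_in_hi) {
        const double *p = src + (size_t)n * M + m;
        for (int k = 0; k < K; ++k) s += p[lin[k]];
        cnt = K;
      } else {
        for (int k = 0; k < K; ++k) {
          int mm = m + dm[k], nn = n + dn[k];
          if (mm < 0 || mm >= M || nn < 0 || nn >= N) continue;
          s += src[(size_t)nn * M + mm]; ++cnt;
        }
      }
      dst[(size_t)n * M + m] = cnt > 0 ? s / cnt : 0.0;
    }
  }
  return out;
}

// Masked windowed mean over a rectangular window given by row/col offset
// ranges [r0, r1] x [c0, c1]; averages only pixels where mask != 0.
// Pixels with an empty valid window get 0.
// [[Rcpp::export]]
NumericMatrix cpp_window_mean_masked(NumericMatrix img, IntegerMatrix mask,
                                     int r0, int r1, int c0, int c1) {
  int M = img.nrow(), N = img.ncol();
  // integral images over img*mask and mask
  std::vector<double> S((size_t)(M + 1) * (N + 1), 0.0);
  std::vector<double> C((size_t)(M + 1) * (N + 1), 0.0);
  for (int n = 0; n < N; ++n) {
    for (int m = 0; m < M; ++m) {
      double v = mask(m, n) ? img(m, n) : 0.0;
      double c = mask(m, n) ? 1.0 : 0.0;
      size_t idx = (size_t)(m + 1) * (N + 1) + (n + 1);
      S[idx] = v + S[idx - (N + 1)] + S[idx - 1] - S[idx - (N + 2)];
      C[idx] = c + C[idx - (N + 1)] + C[idx - 1] - C[idx - (N + 2)];
    }
  }
  NumericMatrix out(M, N);
  for (int n = 0; n < N; ++n) {
    int cl = std::max(0, n + c0), ch = std::min(N - 1, n + c1);
    for (int m = 0; m < M; ++m) {
      int rl = std::max(0, m + r0), rh = std::min(M - 1, m + r1);
      if (rl > rh || cl > ch) { out(m, n) = 0.0; continue; }
      size_t a = (size_t)(rh + 1) * (N + 1) + (ch + 1);
      size_t b = (size_t)rl * (N + 1) + (ch + 1);
      size_t c2 = (size_t)(rh + 1) * (N + 1) + cl;
      size_t d = (size_t)rl * (N + 1) + cl;
      double cnt = C[a] - C[b] - C[c2] + C[d];
      out(m, n) = cnt > 0 ? (S[a] - S[b] - S[c2] + S[d]) / cnt : 0.0;
    }
  }
  return out;
}

// 8-connected component labelling of a binary image (union-find).
// Returns an integer matrix of labels 0 (background), 1..K.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix bw) {
  int M = bw.nrow(), N = bw.ncol();
  IntegerMatrix lab(M, N);
  std::vector<int> parent(1, 0);
  auto find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 1;
  for (int m = 0; m < M; ++m) {
    for (int n = 0; n < N; ++n) {
      if (!bw(m, n)) { lab(m, n) = 0; continue; }
      // previously visited 8-neighbors in raster order
      int neigh[4][2] = {{m, n - 1}, {m - 1, n - 1}, {m - 1, n}, {m - 1, n + 1}};
      int lmin = 0;
      for (int k = 0; k < 4; ++k) {
        int mm = neigh[k][0], nn = neigh[k][1];
        if (mm < 0 || nn < 0 || nn >= N) continue;
        int l = lab(mm, nn);
        if (l > 0 && (lmin == 0 || l < lmin)) lmin = l;
      }
      if (lmin == 0) {
        lab(m, n) = next;
        parent.push_back(next);
        ++next;
      } else {
        lab(m, n) = lmin;
        for (int k = 0; k < 4; ++k) {
          int mm = neigh[k][0], nn = neigh[k][1];
          if (mm < 0 || nn < 0 || nn >= N) continue;
          if (lab(mm, nn) > 0) unite(lab(mm, nn), lmin);
        }
      }
    }
  }
  // compress to consecutive labels
  std::vector<int> remap(next, 0);
  int K = 0;
  for (int m = 0; m < M; ++m) {
    for (int n = 0; n < N; ++n) {
      if (lab(m, n) > 0) {
        int r = find(lab(m, n));
        if (remap[r] == 0) remap[r] = ++K;
        lab(m, n) = remap[r];
      }
    }
  }
  lab.attr("n_objects") = K;
  return lab;
}
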