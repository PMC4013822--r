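#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// 3-D median filter, 3x3x3 neighbourhood, edge replication.
// Works for both 8-bit grey volumes and 0/1 binary volumes.
// [[Rcpp::export]]
IntegerVector med3d_cpp(IntegerVector vol, IntegerVector dim) {
  const int M = dim[0], N = dim[1], I = dim[2];
  IntegerVector out(no_init(vol.size()));
  const int* v = INTEGER(vol);
  int* o = INTEGER(out);
  int buf[27];
  for (int s = 0; s < I; ++s) {
    for (int n = 0; n < N; ++n) {
      for (int m = 0; m < M; ++m) {
        int k = 0;
        for (int ds = -1; ds <= 1; ++ds) {
          const int ss = clampi(s + ds, 0, I - 1);
          for (int dn = -1; dn <= 1; ++dn) {
            const int nn = clampi(n + dn, 0, N - 1);
            const int* base = v + (size_t)M * (nn + (size_t)N * ss);
            buf[k++] = base[clampi(m - 1, 0, M - 1)];
            buf[k++] = base[m];
            buf[k++] = base[clampi(m + 1, 0, M - 1)];
          }
        }
        std::nth_element(buf, buf + 13, buf + 27);
        o[m + (size_t)M * (n + (size_t)N * s)] = buf[13];
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// 2-D median filter with arbitrary odd mask, edge replication.
// [[Rcpp::export]]
NumericMatrix med2d_cpp(NumericMatrix img, int kr, int kc) {
  const int R = img.nrow(), C = img.ncol();
  const int hr = kr / 2, hc = kc / 2;
  NumericMatrix out(R, C);
  std::vector<double> buf((size_t)kr * kc);
  for (int c = 0; c < C; ++c) {
    for (int r = 0; r < R; ++r) {
      size_t k = 0;
      for (int dc = -hc; dc <= hc; ++dc) {
        const int cc = clampi(c + dc, 0, C - 1);
        for (int dr = -hr; dr <= hr; ++dr) {
          buf[k++] = img(clampi(r + dr, 0, R - 1), cc);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + buf.size() / 2, buf.end());
      out(r, c) = buf[buf.size() / 2];
    }
  }
  return out;
}

// Binary morphological closing (dilation then erosion) with a square SE,
// edge replication so image-border object pixels are not eroded away.
// [[Rcpp::export]]
IntegerMatrix closing2d_cpp(IntegerMatrix b, int se) {
  const int R = b.nrow(), C = b.ncol();
  const int h = se / 2;
  IntegerMatrix dil(R, C), out(R, C);
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < R; ++r) {
      int mx = 0;
      for (int dc = -h; dc <= h && !mx; ++dc)
        for (int dr = -h; dr <= h; ++dr)
          if (b(clampi(r + dr, 0, R - 1), clampi(c + dc, 0, C - 1))) { mx = 1; break; }
      dil(r, c) = mx;
    }
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < R; ++r) {
      int mn = 1;
      for (int dc = -h; dc <= h && mn; ++dc)
        for (int dr = -h; dr <= h; ++dr)
          if (!dil(clampi(r + dr, 0, R - 1), clampi(c + dc, 0, C - 1))) { mn = 0; break; }
      out(r, c) = mn;
    }
  return out;
}

// Fill holes (background not reachable 4-connected from the border), then
// label 8-connected components and keep only the largest one (ties: the
// component first met in column-major scan order).
// [[Rcpp::export]]
IntegerMatrix clean_slice_cpp(IntegerMatrix b) {
  const int R = b.nrow(), C = b.ncol();
  IntegerMatrix filled = clone(b);
  std::vector<char> vis((size_t)R * C, 0);
  std::vector<int> stack;
  stack.reserve((size_t)R * C / 4);
  // flood background from border, 4-connectivity
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < R; ++r)
      if ((r == 0 || r == R - 1 || c == 0 || c == C - 1) && b(r, c) == 0 && !vis[r + (size_t)R * c]) {
        stack.push_back(r + R * c);
        vis[r + (size_t)R * c] = 1;
        while (!stack.empty()) {
          int p = stack.back(); stack.pop_back();
          int pr = p % R, pc = p / R;
          const int dr4[4] = {-1, 1, 0, 0}, dc4[4] = {0, 0, -1, 1};
          for (int k = 0; k < 4; ++k) {
            int nr = pr + dr4[k], nc = pc + dc4[k];
            if (nr < 0 || nr >= R || nc < 0 || nc >= C) continue;
            size_t q = nr + (size_t)R * nc;
            if (!vis[q] && b(nr, nc) == 0) { vis[q] = 1; stack.push_back(nr + R * nc); }
          }
        }
      }
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < R; ++r)
      if (b(r, c) == 0 && !vis[r + (size_t)R * c]) filled(r, c) = 1;

  // label 8-connected, track largest
  std::vector<int> lab((size_t)R * C, 0);
  int nlab = 0, best_lab = 0, best_size = 0;
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < R; ++r) {
      size_t p0 = r + (size_t)R * c;
      if (filled(r, c) == 1 && lab[p0] == 0) {
        ++nlab;
        int size = 0;
        stack.clear();
        stack.push_back(r + R * c);
        lab[p0] = nlab;
        while (!stack.empty()) {
          int p = stack.back(); stack.pop_back();
          ++size;
          int pr = p % R, pc = p / R;
          for (int dc = -1; dc <= 1; ++dc)
            for (int dr = -1; dr <= 1; ++dr) {
              if (!dr && !dc) continue;
              int nr = pr + dr, nc = pc + dc;
              if (nr < 0 || nr >= R || nc < 0 || nc >= C) continue;
              size_t q = nr + (size_t)R * nc;
              if (filled(nr, nc) == 1 && lab[q] == 0) { lab[q] = nlab; stack.push_back(nr + R * nc); }
            }
        }
        if (size > best_size) { best_size = size; best_lab = nlab; }
      }
    }
  IntegerMatrix out(R, C);
  if (best_lab > 0)
    for (int c = 0; c < C; ++c)
      for (int r = 0; r < R; ++r)
        out(r, c) = (lab[r + (size_t)R * c] == best_lab) ? 1 : 0;
  return out;
}

// Per-A-scan features on a median-filtered volume:
//   Lef  - first row (1-based) whose intensity exceeds the global threshold pr,
//          NA when the column holds no object pixel;
//   pr2  - modal grey level of the sub-surface column segment (smallest bin wins);
//   pr3  - mean + one (sample) standard deviation of the trailing plateau of
//          the segment. The plateau is located by a two-segment least-squares
//          change point fitting a straight line to the leading part (the
//          A-scan's linear brightness decay through enamel) and a constant to
//          the trailing part (the dentine plateau). Clamped to be >= pr2.
// [[Rcpp::export]]
List column_features_cpp(IntegerVector vol, IntegerVector dim, int pr) {
  const int M = dim[0], N = dim[1], I = dim[2];
  const int* v = INTEGER(vol);
  IntegerMatrix Lef(N, I), pr2(N, I);
  NumericMatrix pr3(N, I);
  std::vector<double> s1(M + 1), s2(M + 1);
  int hist[256];
  for (int s = 0; s < I; ++s) {
    for (int n = 0; n < N; ++n) {
      const int* col = v + (size_t)M * (n + (size_t)N * s);
      int ef = -1;
      for (int m = 0; m < M; ++m)
        if (col[m] > pr) { ef = m; break; }
      if (ef < 0) {
        Lef(n, s) = NA_INTEGER; pr2(n, s) = NA_INTEGER; pr3(n, s) = NA_REAL;
        continue;
      }
      Lef(n, s) = ef + 1;
      const int L = M - ef;
      std::fill(hist, hist + 256, 0);
      for (int m = ef; m < M; ++m) ++hist[col[m] & 255];
      int mode = 0;
      for (int b = 1; b < 256; ++b) if (hist[b] > hist[mode]) mode = b;
      pr2(n, s) = mode;
      // change point: line (part I decay) + constant (part II plateau)
      s1[0] = 0.0; s2[0] = 0.0;
      double sxy = 0.0;
      std::vector<double> s3(M + 1);
      s3[0] = 0.0;
      for (int k = 0; k < L; ++k) {
        const double y = (double)col[ef + k];
        const double x = (double)(k + 1);
        s1[k + 1] = s1[k] + y;
        s2[k + 1] = s2[k] + y * y;
        s3[k + 1] = s3[k] + x * y;
      }
      int t0 = 0;  // first-segment length; 0 => plateau is whole segment
      if (L >= 4) {
        double best = R_PosInf;
        for (int t = 2; t <= L - 2; ++t) {
          const double td = (double)t;
          const double sx = td * (td + 1) / 2.0;
          const double sxx = td * (td + 1) * (2 * td + 1) / 6.0;
          const double cxx = sxx - sx * sx / td;
          const double cxy = s3[t] - sx * s1[t] / td;
          const double rss1 = (s2[t] - s1[t] * s1[t] / td) -
            (cxx > 0 ? cxy * cxy / cxx : 0.0);
          const double a2 = s1[L] - s1[t], b2 = s2[L] - s2[t];
          const double rss2 = b2 - a2 * a2 / (L - t);
          const double cost = rss1 + rss2;
          if (cost < best) { best = cost; t0 = t; }
        }
      }
      const int Ls = L - t0;
      const double mu = (s1[L] - s1[t0]) / Ls;
      double sd = 0.0;
      if (Ls >= 2) {
        double ss = (s2[L] - s2[t0]) - Ls * mu * mu;
        if (ss < 0) ss = 0;
        sd = std::sqrt(ss / (Ls - 1));
      }
      double p3 = mu + sd;
      if (p3 < mode) p3 = mode;
      pr3(n, s) = p3;
    }
  }
  return List::create(_["L_ef"] = Lef, _["p_r2"] = pr2, _["p_r3"] = pr3);
}

// Deepest row (1-based, exclusive convention: last row above threshold + 1)
// with intensity > thr, searching from row `from` (1-based) downwards.
// Used by the p_r2/p_r3 disambiguation fallback. NA when none.
// [[Rcpp::export]]
IntegerMatrix deepest_above_cpp(IntegerVector vol, IntegerVector dim,
                                NumericMatrix thr, IntegerMatrix from) {
  const int M = dim[0], N = dim[1], I = dim[2];
  const int* v = INTEGER(vol);
  IntegerMatrix out(N, I);
  for (int s = 0; s < I; ++s)
    for (int n = 0; n < N; ++n) {
      if (from(n, s) == NA_INTEGER || ISNA(thr(n, s))) { out(n, s) = NA_INTEGER; continue; }
      const int* col = v + (size_t)M * (n + (size_t)N * s);
      int deep = NA_INTEGER;
      for (int m = M - 1; m >= from(n, s) - 1; --m)
        if ((double)col[m] > thr(n, s)) { deep = m + 2; break; }
      out(n, s) = deep;
    }
  return out;
}

// Full shift surface of the match criterion J for one pre-zoomed moving
// image: J(dn,di) = mean over the whole grid of |ref - Z(n+dn, i+di)| with
// zero written outside Z. ref and zmov are N x I (rows = columns n,
// cols = B-scan index i), both assumed non-negative (normalized [0,1]).
// Returns a (2K+1) x (2K+1) matrix indexed [dn+K+1, di+K+1].
// [[Rcpp::export]]
NumericMatrix j_surface_cpp(NumericMatrix ref, NumericMatrix zmov, int K) {
  const int N = ref.nrow(), I = ref.ncol();
  // prefix sums of ref (non-negative)
  NumericMatrix P(N + 1, I + 1);
  double T = 0.0;
  for (int i = 0; i < I; ++i)
    for (int n = 0; n < N; ++n) {
      P(n + 1, i + 1) = ref(n, i) + P(n, i + 1) + P(n + 1, i) - P(n, i);
    }
  T = P(N, I);
  NumericMatrix J(2 * K + 1, 2 * K + 1);
  for (int di = -K; di <= K; ++di) {
    const int i0 = std::max(0, -di), i1 = std::min(I, I - di);  // [i0, i1)
    for (int dn = -K; dn <= K; ++dn) {
      const int n0 = std::max(0, -dn), n1 = std::min(N, N - dn);
      double acc = 0.0, rect = 0.0;
      if (n1 > n0 && i1 > i0) {
        for (int i = i0; i < i1; ++i) {
          const double* zc = &zmov(0, i + di);
          const double* rc = &ref(0, i);
          for (int n = n0; n < n1; ++n) acc += std::fabs(rc[n] - zc[n + dn]);
        }
        rect = P(n1, i1) - P(n0, i1) - P(n1, i0) + P(n0, i0);
      }
      J(dn + K, di + K) = (acc + (T - rect)) / ((double)N * I);
    }
  }
  return J;
}
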