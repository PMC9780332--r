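#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// 8-connected component labeling of a logical mask.
// EBImage::bwlabel is 4-connected; cells and foci here are defined on
// 8-connectivity, so we label ourselves.
// [[Rcpp::export(name = ".label8_cpp")]]
IntegerMatrix label8_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ii = p.first + di, jj = p.second + dj;
            if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              q.push(std::make_pair(ii, jj));
            }
          }
        }
      }
    }
  }
  return lab;
}

static inline int clampi(int v, int hi) {
  return v < 0 ? 0 : (v > hi ? hi : v);
}

// Non-flat grayscale erosion: out(p) = min_q [ img(p+q) - h(q) ].
// Borders are replicate-extended (coordinates clamped), so a flat image
// opens to itself exactly up to the edge.
// [[Rcpp::export(name = ".gray_erode_cpp")]]
NumericMatrix gray_erode_cpp(const NumericMatrix& img,
                             const IntegerVector& di, const IntegerVector& dj,
                             const NumericVector& h) {
  const int nr = img.nrow(), nc = img.ncol(), K = di.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double m = R_PosInf;
      for (int k = 0; k < K; ++k) {
        int ii = clampi(i + di[k], nr - 1), jj = clampi(j + dj[k], nc - 1);
        double v = img(ii, jj) - h[k];
        if (v < m) m = v;
      }
      out(i, j) = m;
    }
  }
  return out;
}

// Non-flat grayscale dilation: out(p) = max_q [ img(p-q) + h(q) ].
// [[Rcpp::export(name = ".gray_dilate_cpp")]]
NumericMatrix gray_dilate_cpp(const NumericMatrix& img,
                              const IntegerVector& di, const IntegerVector& dj,
                              const NumericVector& h) {
  const int nr = img.nrow(), nc = img.ncol(), K = di.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double m = R_NegInf;
      for (int k = 0; k < K; ++k) {
        int ii = clampi(i - di[k], nr - 1), jj = clampi(j - dj[k], nc - 1);
        double v = img(ii, jj) + h[k];
        if (v > m) m = v;
      }
      out(i, j) = m;
    }
  }
  return out;
}

// Block-minimum downsampling by integer factor s (ImageJ-style shrink before
// rolling the ball; the minimum preserves the background envelope).
// [[Rcpp::export(name = ".block_min_cpp")]]
NumericMatrix block_min_cpp(const NumericMatrix& img, int s) {
  const int nr = img.nrow(), nc = img.ncol();
  const int mr = (nr + s - 1) / s, mc = (nc + s - 1) / s;
  NumericMatrix out(mr, mc);
  for (int bj = 0; bj < mc; ++bj) {
    for (int bi = 0; bi < mr; ++bi) {
      double m = R_PosInf;
      for (int j = bj * s; j < std::min((bj + 1) * s, nc); ++j)
        for (int i = bi * s; i < std::min((bi + 1) * s, nr); ++i)
          if (img(i, j) < m) m = img(i, j);
      out(bi, bj) = m;
    }
  }
  return out;
}

// Bilinear upsampling of a shrunk background to full resolution. Small-image
// pixel (bi,bj) is taken to sit at full-resolution position bi*s + (s-1)/2.
// [[Rcpp::export(name = ".bilinear_expand_cpp")]]
NumericMatrix bilinear_expand_cpp(const NumericMatrix& small, int nr, int nc,
                                  int s) {
  const int mr = small.nrow(), mc = small.ncol();
  const double off = (s - 1) / 2.0;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    double y = (j - off) / s;
    int j0 = (int)std::floor(y);
    double fy = y - j0;
    if (j0 < 0) { j0 = 0; fy = 0.0; }
    if (j0 >= mc - 1) { j0 = mc - 1; fy = 0.0; }
    int j1 = std::min(j0 + 1, mc - 1);
    for (int i = 0; i < nr; ++i) {
      double x = (i - off) / s;
      int i0 = (int)std::floor(x);
      double fx = x - i0;
      if (i0 < 0) { i0 = 0; fx = 0.0; }
      if (i0 >= mr - 1) { i0 = mr - 1; fx = 0.0; }
      int i1 = std::min(i0 + 1, mr - 1);
      out(i, j) = (1 - fx) * (1 - fy) * small(i0, j0) +
                  fx * (1 - fy) * small(i1, j0) +
                  (1 - fx) * fy * small(i0, j1) +
                  fx * fy * small(i1, j1);
    }
  }
  return out;
}

static inline int nb(const LogicalMatrix& m, int i, int j) {
  if (i < 0 || j < 0 || i >= m.nrow() || j >= m.ncol()) return 0;
  return m(i, j) ? 1 : 0;
}

// Guo-Hall thinning; returns the 8-connected skeleton of a binary mask.
// (More isotropic than Zhang-Suen, which can over-erode thick shapes
// oriented near 45 degrees.)
// [[Rcpp::export(name = ".thin_cpp")]]
LogicalMatrix thin_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix m = clone(mask);
  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!m(i, j)) continue;
          // neighbours P2..P9 clockwise from north (row-1)
          int p2 = nb(m, i - 1, j),     p3 = nb(m, i - 1, j + 1);
          int p4 = nb(m, i, j + 1),     p5 = nb(m, i + 1, j + 1);
          int p6 = nb(m, i + 1, j),     p7 = nb(m, i + 1, j - 1);
          int p8 = nb(m, i, j - 1),     p9 = nb(m, i - 1, j - 1);
          int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
                  ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
          int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
          int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
          int N = N1 < N2 ? N1 : N2;
          int mm = (pass == 0) ? ((p6 | p7 | (!p9)) & p8)
                               : ((p2 | p3 | (!p5)) & p4);
          if (C == 1 && N >= 2 && N <= 3 && mm == 0)
            kill.push_back(std::make_pair(i, j));
        }
      }
      for (size_t k = 0; k < kill.size(); ++k)
        m(kill[k].first, kill[k].second) = false;
      if (!kill.empty()) changed = true;
    }
  }
  return m;
}
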