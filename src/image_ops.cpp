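#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

// Low-level raster primitives used by nucleus segmentation and spot
// detection. All matrices are column-major (R layout); coordinates are
// (row, col), 1-based on the R side.

// Connected-component labelling of a binary mask by breadth-first search.
// connectivity: 4 or 8. Labels are assigned in raster (column-major) order
// of the first pixel encountered, so the result is deterministic.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity = 8) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  std::vector<int> stack;
  int next_label = 0;
  int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nnb = (connectivity == 4) ? 4 : 8;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || out(r, c) != 0) continue;
      ++next_label;
      out(r, c) = next_label;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int r2 = rr + dr8[k], c2 = cc + dc8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && out(r2, c2) == 0) {
            out(r2, c2) = next_label;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return out;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher).
static void dt1d(std::vector<double>& f, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Exact squared Euclidean distance of every foreground pixel to the nearest
// background pixel (0 on background).
// [[Rcpp::export(name = ".edt_sq")]]
NumericMatrix edt_sq(LogicalMatrix mask) {
  // large finite stand-in for "no background seen yet": infinity would
  // produce INF - INF = NaN inside the parabola intersection formula
  const double BIG = 1e20;
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = mask(r, c) ? BIG : 0.0;
  std::vector<double> buf(std::max(nr, nc));
  // columns
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) buf[r] = out(r, c);
    dt1d(buf, nr);
    for (int r = 0; r < nr; ++r) out(r, c) = buf[r];
  }
  // rows
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) buf[c] = out(r, c);
    dt1d(buf, nc);
    for (int c = 0; c < nc; ++c) out(r, c) = buf[c];
  }
  return out;
}

// Sliding-window maximum over a (2r+1) square window, used for plateau-aware
// local-maximum detection. Brute force; r is small in practice.
// [[Rcpp::export(name = ".window_max")]]
NumericMatrix window_max(NumericMatrix m, int r) {
  int nr = m.nrow(), nc = m.ncol();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    int c0 = std::max(0, c - r), c1 = std::min(nc - 1, c + r);
    for (int rr = 0; rr < nr; ++rr) {
      int r0 = std::max(0, rr - r), r1 = std::min(nr - 1, rr + r);
      double best = -std::numeric_limits<double>::infinity();
      for (int cc = c0; cc <= c1; ++cc)
        for (int r2 = r0; r2 <= r1; ++r2)
          if (m(r2, cc) > best) best = m(r2, cc);
      out(rr, c) = best;
    }
  }
  return out;
}

struct QNode {
  double alt;
  long order;
  int idx;
};
struct QNodeCmp {
  bool operator()(const QNode& a, const QNode& b) const {
    if (a.alt != b.alt) return a.alt > b.alt;   // min-heap on altitude
    return a.order > b.order;                   // FIFO tie-break
  }
};

// Marker-driven priority flood ("watershed without lines"): regions grow from
// the marker pixels in increasing order of `altitude`, restricted to `mask`.
// For nucleus splitting, altitude = -distance transform.
// [[Rcpp::export(name = ".priority_flood")]]
IntegerMatrix priority_flood(NumericMatrix altitude, LogicalMatrix mask,
                             IntegerMatrix markers) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  std::priority_queue<QNode, std::vector<QNode>, QNodeCmp> pq;
  long order = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (markers(r, c) > 0 && mask(r, c)) {
        out(r, c) = markers(r, c);
        pq.push({altitude(r, c), order++, r + c * nr});
      }
  int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  while (!pq.empty()) {
    QNode nd = pq.top(); pq.pop();
    int r = nd.idx % nr, c = nd.idx / nr;
    int lab = out(r, c);
    for (int k = 0; k < 8; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (mask(r2, c2) && out(r2, c2) == 0) {
        out(r2, c2) = lab;
        pq.push({altitude(r2, c2), order++, r2 + c2 * nr});
      }
    }
  }
  return out;
}

// Expand a label image outward by up to `radius` pixels: every unlabelled
// pixel takes the label of the nearest labelled pixel within the radius,
// keeping the expanded regions of different labels disjoint. Ties are broken
// by scan order (deterministic).
// [[Rcpp::export(name = ".nearest_label_within")]]
IntegerMatrix nearest_label_within(IntegerMatrix labels, double radius) {
  int nr = labels.nrow(), nc = labels.ncol();
  IntegerMatrix out = clone(labels);
  int r = (int)std::floor(radius);
  if (r < 1) return out;
  double r2max = radius * radius;
  for (int c = 0; c < nc; ++c) {
    for (int rr = 0; rr < nr; ++rr) {
      if (labels(rr, c) != 0) continue;
      double best = r2max + 1.0;
      int best_lab = 0;
      int c0 = std::max(0, c - r), c1 = std::min(nc - 1, c + r);
      int r0 = std::max(0, rr - r), r1 = std::min(nr - 1, rr + r);
      for (int cc = c0; cc <= c1; ++cc) {
        for (int rx = r0; rx <= r1; ++rx) {
          int lab = labels(rx, cc);
          if (lab == 0) continue;
          double d2 = (double)(rx - rr) * (rx - rr) +
                      (double)(cc - c) * (cc - c);
          if (d2 <= r2max && d2 < best) { best = d2; best_lab = lab; }
        }
      }
      out(rr, c) = best_lab;
    }
  }
  return out;
}

// Paint anti-aliased filled discs onto an image by max-composition.
// cx, cy are 1-based pixel-centre coordinates (col, row), radius in pixels,
// value per disc; edge softness ~0.5 px via a clamped linear ramp.
// [[Rcpp::export(name = ".paint_discs")]]
NumericMatrix paint_discs(NumericMatrix img, NumericVector cx, NumericVector cy,
                          NumericVector radius, NumericVector value,
                          double edge = 0.75) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out = clone(img);
  int n = cx.size();
  for (int i = 0; i < n; ++i) {
    double x = cx[i] - 1.0, y = cy[i] - 1.0, rad = radius[i], v = value[i];
    int c0 = std::max(0, (int)std::floor(x - rad - edge));
    int c1 = std::min(nc - 1, (int)std::ceil(x + rad + edge));
    int r0 = std::max(0, (int)std::floor(y - rad - edge));
    int r1 = std::min(nr - 1, (int)std::ceil(y + rad + edge));
    for (int c = c0; c <= c1; ++c) {
      for (int r = r0; r <= r1; ++r) {
        double d = std::sqrt((c - x) * (c - x) + (r - y) * (r - y));
        double w = (rad + edge / 2.0 - d) / edge;  // 1 inside, 0 outside
        if (w <= 0) continue;
        if (w > 1) w = 1;
        double val = v * w;
        if (val > out(r, c)) out(r, c) = val;
      }
    }
  }
  return out;
}
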