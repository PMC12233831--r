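#include <Rcpp.h>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// Disc offsets sorted by increasing Euclidean distance; ties broken by
// (dy, dx) so every scan is deterministic across platforms.
struct Offset {
  int dy, dx;
  double d;
};

static std::vector<Offset> disc_offsets(int radius, bool include_centre) {
  std::vector<Offset> off;
  for (int dy = -radius; dy <= radius; ++dy) {
    for (int dx = -radius; dx <= radius; ++dx) {
      double d = std::sqrt((double)(dy * dy + dx * dx));
      if (d > radius + 1e-9) continue;
      if (!include_centre && dy == 0 && dx == 0) continue;
      off.push_back({dy, dx, d});
    }
  }
  std::sort(off.begin(), off.end(), [](const Offset& a, const Offset& b) {
    if (a.d != b.d) return a.d < b.d;
    if (a.dy != b.dy) return a.dy < b.dy;
    return a.dx < b.dx;
  });
  return off;
}

// 8-connected component labelling of a logical mask, labels 1..k in
// raster-scan discovery order.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dx = -1; dx <= 1; ++dx) {
            int y = p.first + dy, x = p.second + dx;
            if (y < 0 || y >= nr || x < 0 || x >= nc) continue;
            if (mask(y, x) && lab(y, x) == 0) {
              lab(y, x) = next;
              stack.push_back(std::make_pair(y, x));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Grayscale erosion (min) / dilation (max) with a disc structuring element.
// [[Rcpp::export(name = ".grey_morph")]]
NumericMatrix grey_morph(NumericMatrix img, int radius, bool dilate) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  std::vector<Offset> off = disc_offsets(radius, true);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = img(i, j);
      for (size_t k = 0; k < off.size(); ++k) {
        int y = i + off[k].dy, x = j + off[k].dx;
        if (y < 0 || y >= nr || x < 0 || x >= nc) continue;
        double w = img(y, x);
        if (dilate ? (w > v) : (w < v)) v = w;
      }
      out(i, j) = v;
    }
  }
  return out;
}

// Exact Euclidean distance from each true pixel to the nearest false pixel
// (or image border), capped at max_radius. Background pixels get 0.
// [[Rcpp::export(name = ".dist_to_background")]]
NumericMatrix dist_to_background(LogicalMatrix mask, int max_radius) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix out(nr, nc);
  std::vector<Offset> off = disc_offsets(max_radius, false);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) { out(i, j) = 0.0; continue; }
      double d = max_radius;
      for (size_t k = 0; k < off.size(); ++k) {
        int y = i + off[k].dy, x = j + off[k].dx;
        bool bg = (y < 0 || y >= nr || x < 0 || x >= nc) || !mask(y, x);
        if (bg) { d = off[k].d; break; }
      }
      out(i, j) = d;
    }
  }
  return out;
}

// Expand every labelled object isotropically by `radius` pixels; collisions
// are resolved by the nearest seed pixel (exact Euclidean, deterministic
// tie-break by scan order), i.e. a distance-limited Voronoi partition.
// [[Rcpp::export(name = ".expand_labels")]]
IntegerMatrix expand_labels(IntegerMatrix lab, int radius) {
  int nr = lab.nrow(), nc = lab.ncol();
  IntegerMatrix out(nr, nc);
  NumericMatrix best(nr, nc);
  std::fill(best.begin(), best.end(), R_PosInf);
  std::vector<Offset> off = disc_offsets(radius, true);
  // scatter from each labelled pixel: nearest seed pixel wins (exact
  // Euclidean; ties broken by seed scan order, deterministically)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      for (size_t k = 0; k < off.size(); ++k) {
        int y = i + off[k].dy, x = j + off[k].dx;
        if (y < 0 || y >= nr || x < 0 || x >= nc) continue;
        if (lab(y, x) != 0) continue;
        if (off[k].d < best(y, x)) { best(y, x) = off[k].d; out(y, x) = l; }
      }
    }
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) != 0) out(i, j) = lab(i, j);
  return out;
}

// Seeded watershed by priority flooding on an elevation map (higher floods
// first; pass the distance transform to split touching convex objects).
// Only pixels inside `mask` are assigned.
struct QItem {
  double elev;
  long order;
  int i, j, label;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.elev != b.elev) return a.elev < b.elev; // max-heap on elevation
    return a.order > b.order;                     // FIFO among equals
  }
};

// [[Rcpp::export(name = ".watershed_flood")]]
IntegerMatrix watershed_flood(NumericMatrix elev, IntegerMatrix seeds,
                              LogicalMatrix mask) {
  int nr = elev.nrow(), nc = elev.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  long ord = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (seeds(i, j) != 0 && mask(i, j)) {
        lab(i, j) = seeds(i, j);
        pq.push({elev(i, j), ord++, i, j, seeds(i, j)});
      }
  while (!pq.empty()) {
    QItem q = pq.top();
    pq.pop();
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        int y = q.i + dy, x = q.j + dx;
        if (y < 0 || y >= nr || x < 0 || x >= nc) continue;
        if (!mask(y, x) || lab(y, x) != 0) continue;
        lab(y, x) = q.label;
        pq.push({elev(y, x), ord++, y, x, q.label});
      }
    }
  }
  return lab;
}
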