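#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// ---- union-find over face adjacency -------------------------------------

static inline int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]]; // path halving
    x = parent[x];
  }
  return x;
}

// Root label (1-based) of every node after merging all edges.
// [[Rcpp::export]]
IntegerVector uf_components(IntegerMatrix edges, int n) {
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  const int m = edges.nrow();
  for (int e = 0; e < m; ++e) {
    int a = uf_find(parent, edges(e, 0) - 1);
    int b = uf_find(parent, edges(e, 1) - 1);
    if (a != b) parent[b] = a;
  }
  IntegerVector root(n);
  for (int i = 0; i < n; ++i) root[i] = uf_find(parent, i) + 1;
  return root;
}

// ---- fixed-radius neighbor counting (hashed uniform grid) ----------------

static inline long long grid_key(double x, double y, double z, double h) {
  long long ix = (long long)std::floor(x / h);
  long long iy = (long long)std::floor(y / h);
  long long iz = (long long)std::floor(z / h);
  return (ix * 73856093LL) ^ (iy * 19349663LL) ^ (iz * 83492791LL);
}

typedef std::unordered_map<long long, std::vector<int> > GridMap;

static GridMap build_grid(const NumericMatrix &pts, double h) {
  GridMap grid;
  grid.reserve((size_t)pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i)
    grid[grid_key(pts(i, 0), pts(i, 1), pts(i, 2), h)].push_back(i);
  return grid;
}

// Distinct hash keys of the 27 cells around (x, y, z). Hash collisions
// between distinct cells would otherwise scan a merged bucket twice and
// double-count neighbors.
static int probe_keys(double x, double y, double z, double h,
                      long long keys[27]) {
  int nk = 0;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        long long key = grid_key(x + dx * h, y + dy * h, z + dz * h, h);
        bool seen = false;
        for (int q = 0; q < nk; ++q)
          if (keys[q] == key) { seen = true; break; }
        if (!seen) keys[nk++] = key;
      }
  return nk;
}

// Number of other points of `pts` within `radius` of each point (<= radius).
// [[Rcpp::export]]
IntegerVector neighbor_counts(NumericMatrix pts, double radius) {
  const int n = pts.nrow();
  IntegerVector out(n);
  if (n == 0) return out;
  GridMap grid = build_grid(pts, radius);
  const double r2 = radius * radius;
  long long keys[27];
  for (int i = 0; i < n; ++i) {
    const double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    int cnt = 0;
    int nk = probe_keys(x, y, z, radius, keys);
    for (int q = 0; q < nk; ++q) {
      GridMap::const_iterator it = grid.find(keys[q]);
      if (it == grid.end()) continue;
      const std::vector<int> &cell = it->second;
      for (size_t k = 0; k < cell.size(); ++k) {
        int j = cell[k];
        if (j == i) continue;
        double ddx = pts(j, 0) - x, ddy = pts(j, 1) - y,
               ddz = pts(j, 2) - z;
        if (ddx * ddx + ddy * ddy + ddz * ddz <= r2) ++cnt;
      }
    }
    out[i] = cnt;
  }
  return out;
}

// Number of points of `ref` within `radius` of each query point.
// [[Rcpp::export]]
IntegerVector cross_neighbor_counts(NumericMatrix query, NumericMatrix ref,
                                    double radius) {
  const int n = query.nrow();
  IntegerVector out(n);
  if (n == 0 || ref.nrow() == 0) return out;
  GridMap grid = build_grid(ref, radius);
  const double r2 = radius * radius;
  long long keys[27];
  for (int i = 0; i < n; ++i) {
    const double x = query(i, 0), y = query(i, 1), z = query(i, 2);
    int cnt = 0;
    int nk = probe_keys(x, y, z, radius, keys);
    for (int q = 0; q < nk; ++q) {
      GridMap::const_iterator it = grid.find(keys[q]);
      if (it == grid.end()) continue;
      const std::vector<int> &cell = it->second;
      for (size_t k = 0; k < cell.size(); ++k) {
        int j = cell[k];
        double ddx = ref(j, 0) - x, ddy = ref(j, 1) - y,
               ddz = ref(j, 2) - z;
        if (ddx * ddx + ddy * ddy + ddz * ddz <= r2) ++cnt;
      }
    }
    out[i] = cnt;
  }
  return out;
}

// ---- point-in-mesh by vertical ray parity --------------------------------
//
// Casts a +z ray from each query point and counts crossings with the
// triangle soup. Queries are nudged off lattice-aligned edges by a tiny
// irrational offset so the strict-interior test is parity-safe for
// grid-aligned meshes.
// [[Rcpp::export]]
LogicalVector points_in_mesh(NumericMatrix v, IntegerMatrix f,
                             NumericMatrix q) {
  const int nf = f.nrow(), nq = q.nrow();
  LogicalVector out(nq);
  std::vector<double> x1(nf), y1(nf), z1(nf), x2(nf), y2(nf), z2(nf),
      x3(nf), y3(nf), z3(nf), xmin(nf), xmax(nf), ymin(nf), ymax(nf),
      den(nf);
  for (int t = 0; t < nf; ++t) {
    int a = f(t, 0) - 1, b = f(t, 1) - 1, c = f(t, 2) - 1;
    x1[t] = v(a, 0); y1[t] = v(a, 1); z1[t] = v(a, 2);
    x2[t] = v(b, 0); y2[t] = v(b, 1); z2[t] = v(b, 2);
    x3[t] = v(c, 0); y3[t] = v(c, 1); z3[t] = v(c, 2);
    xmin[t] = std::min(x1[t], std::min(x2[t], x3[t]));
    xmax[t] = std::max(x1[t], std::max(x2[t], x3[t]));
    ymin[t] = std::min(y1[t], std::min(y2[t], y3[t]));
    ymax[t] = std::max(y1[t], std::max(y2[t], y3[t]));
    den[t] = (y2[t] - y3[t]) * (x1[t] - x3[t]) +
             (x3[t] - x2[t]) * (y1[t] - y3[t]);
  }
  const double ex = 7.23e-8, ey = 3.11e-8;
  for (int i = 0; i < nq; ++i) {
    const double px = q(i, 0) + ex, py = q(i, 1) + ey, pz = q(i, 2);
    int crossings = 0;
    for (int t = 0; t < nf; ++t) {
      if (px < xmin[t] || px > xmax[t] || py < ymin[t] || py > ymax[t])
        continue;
      double d = den[t];
      if (std::fabs(d) < 1e-18) continue; // vertical triangle: grazing
      double l1 = ((y2[t] - y3[t]) * (px - x3[t]) +
                   (x3[t] - x2[t]) * (py - y3[t])) / d;
      double l2 = ((y3[t] - y1[t]) * (px - x3[t]) +
                   (x1[t] - x3[t]) * (py - y3[t])) / d;
      double l3 = 1.0 - l1 - l2;
      if (l1 <= 0.0 || l2 <= 0.0 || l3 <= 0.0) continue;
      double zh = l1 * z1[t] + l2 * z2[t] + l3 * z3[t];
      if (zh > pz) ++crossings;
    }
    out[i] = (crossings % 2) == 1;
  }
  return out;
}
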