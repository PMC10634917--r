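#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <deque>
#include <limits>
#include <map>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// DBSCAN with grid-accelerated fixed-radius neighbor search.
//
// Semantics follow the textbook algorithm: a point is core if its closed
// eps-neighborhood (including itself) has >= minPts members; clusters are
// grown from core points in ascending index order; border points are claimed
// by the first cluster that reaches them. Labels: 0 = noise, 1..k = clusters.
// The control flow is mirrored exactly by the pure-R brute-force oracle used
// in the tests, so labels agree verbatim.
// ---------------------------------------------------------------------------

struct Grid {
  double xmin, ymin, cell;
  int ncx, ncy;
  std::vector<std::vector<int> > buckets;
  Grid(const NumericVector& x, const NumericVector& y, double eps) {
    int n = x.size();
    xmin = *std::min_element(x.begin(), x.end());
    ymin = *std::min_element(y.begin(), y.end());
    double xmax = *std::max_element(x.begin(), x.end());
    double ymax = *std::max_element(y.begin(), y.end());
    cell = eps > 0 ? eps : 1.0;
    ncx = (int)std::floor((xmax - xmin) / cell) + 1;
    ncy = (int)std::floor((ymax - ymin) / cell) + 1;
    buckets.resize((size_t)ncx * ncy);
    for (int i = 0; i < n; ++i) {
      int cx = (int)std::floor((x[i] - xmin) / cell);
      int cy = (int)std::floor((y[i] - ymin) / cell);
      buckets[(size_t)cx * ncy + cy].push_back(i);
    }
  }
  // neighbors of point i within eps (closed ball), ascending index order
  void neighbors(const NumericVector& x, const NumericVector& y,
                 int i, double eps2, std::vector<int>& out) const {
    out.clear();
    int cx = (int)std::floor((x[i] - xmin) / cell);
    int cy = (int)std::floor((y[i] - ymin) / cell);
    for (int dx = -1; dx <= 1; ++dx) {
      int gx = cx + dx;
      if (gx < 0 || gx >= ncx) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int gy = cy + dy;
        if (gy < 0 || gy >= ncy) continue;
        const std::vector<int>& b = buckets[(size_t)gx * ncy + gy];
        for (size_t k = 0; k < b.size(); ++k) {
          int j = b[k];
          double ddx = x[j] - x[i], ddy = y[j] - y[i];
          if (ddx * ddx + ddy * ddy <= eps2) out.push_back(j);
        }
      }
    }
    std::sort(out.begin(), out.end());
  }
};

// [[Rcpp::export]]
IntegerVector dbscan_impl(NumericVector x, NumericVector y,
                          double eps, int minPts) {
  int n = x.size();
  IntegerVector labels(n, 0);
  if (n == 0) return labels;
  Grid grid(x, y, eps);
  double eps2 = eps * eps;
  std::vector<bool> visited(n, false);
  std::vector<int> nb, nb2;
  int cid = 0;
  for (int i = 0; i < n; ++i) {
    if (visited[i]) continue;
    visited[i] = true;
    grid.neighbors(x, y, i, eps2, nb);
    if ((int)nb.size() < minPts) continue;  // noise (may be claimed later)
    ++cid;
    labels[i] = cid;
    std::deque<int> queue(nb.begin(), nb.end());
    while (!queue.empty()) {
      int j = queue.front();
      queue.pop_front();
      if (labels[j] == 0) labels[j] = cid;
      if (visited[j]) continue;
      visited[j] = true;
      grid.neighbors(x, y, j, eps2, nb2);
      if ((int)nb2.size() >= minPts)
        queue.insert(queue.end(), nb2.begin(), nb2.end());
    }
  }
  return labels;
}

// ---------------------------------------------------------------------------
// Delaunay triangulation (Bowyer-Watson). Coordinates are rescaled to the
// unit box internally; the caller is responsible for removing duplicate
// points (and may apply a symbolic micro-jitter against co-circularity).
// Returns a 0-based integer matrix of triangle vertex indices.
// ---------------------------------------------------------------------------

struct Tri {
  int a, b, c;
  double cx, cy, r2;
  bool alive;
};

static void circumcircle(double ax, double ay, double bx, double by,
                         double cx, double cy, double& ox, double& oy,
                         double& r2) {
  double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
  if (std::fabs(d) < 1e-300) {  // degenerate: infinite circumcircle
    ox = oy = 0.0;
    r2 = std::numeric_limits<double>::infinity();
    return;
  }
  double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by, c2 = cx * cx + cy * cy;
  ox = (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d;
  oy = (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d;
  double dx = ax - ox, dy = ay - oy;
  r2 = dx * dx + dy * dy;
}

// [[Rcpp::export]]
IntegerMatrix delaunay_impl(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n < 3) stop("need at least 3 points");
  // rescale to unit box
  double xmin = *std::min_element(x.begin(), x.end());
  double xmax = *std::max_element(x.begin(), x.end());
  double ymin = *std::min_element(y.begin(), y.end());
  double ymax = *std::max_element(y.begin(), y.end());
  double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0) stop("degenerate point set");
  std::vector<double> px(n + 3), py(n + 3);
  for (int i = 0; i < n; ++i) {
    px[i] = (x[i] - xmin) / span;
    py[i] = (y[i] - ymin) / span;
  }
  // super-triangle well outside the unit box
  px[n] = -100.0;  py[n] = -100.0;
  px[n + 1] = 100.0; py[n + 1] = -100.0;
  px[n + 2] = 0.0;  py[n + 2] = 200.0;

  std::vector<Tri> tris;
  {
    Tri t;
    t.a = n; t.b = n + 1; t.c = n + 2; t.alive = true;
    circumcircle(px[t.a], py[t.a], px[t.b], py[t.b], px[t.c], py[t.c],
                 t.cx, t.cy, t.r2);
    tris.push_back(t);
  }

  std::vector<int> bad;
  typedef std::pair<int, int> Edge;
  for (int ip = 0; ip < n; ++ip) {
    double qx = px[ip], qy = py[ip];
    bad.clear();
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!tris[t].alive) continue;
      double dx = qx - tris[t].cx, dy = qy - tris[t].cy;
      if (dx * dx + dy * dy <= tris[t].r2 * (1.0 + 1e-12))
        bad.push_back((int)t);
    }
    // cavity boundary: edges of bad triangles occurring exactly once
    std::map<Edge, int> ecount;
    std::map<Edge, Edge> eorient;  // keep original orientation
    for (size_t k = 0; k < bad.size(); ++k) {
      const Tri& t = tris[bad[k]];
      int vs[3][2] = { {t.a, t.b}, {t.b, t.c}, {t.c, t.a} };
      for (int e = 0; e < 3; ++e) {
        Edge key(std::min(vs[e][0], vs[e][1]), std::max(vs[e][0], vs[e][1]));
        ecount[key] += 1;
        eorient[key] = Edge(vs[e][0], vs[e][1]);
      }
      tris[bad[k]].alive = false;
    }
    for (std::map<Edge, int>::iterator it = ecount.begin();
         it != ecount.end(); ++it) {
      if (it->second != 1) continue;
      Edge o = eorient[it->first];
      Tri t;
      t.a = o.first; t.b = o.second; t.c = ip; t.alive = true;
      circumcircle(px[t.a], py[t.a], px[t.b], py[t.b], px[t.c], py[t.c],
                   t.cx, t.cy, t.r2);
      tris.push_back(t);
    }
  }

  std::vector<int> keep;
  for (size_t t = 0; t < tris.size(); ++t) {
    if (!tris[t].alive) continue;
    if (tris[t].a >= n || tris[t].b >= n || tris[t].c >= n) continue;
    keep.push_back((int)t);
  }
  IntegerMatrix out(keep.size(), 3);
  for (size_t k = 0; k < keep.size(); ++k) {
    out(k, 0) = tris[keep[k]].a;
    out(k, 1) = tris[keep[k]].b;
    out(k, 2) = tris[keep[k]].c;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Point-in-polygon, boundary-inclusive, even-odd rule over multiple rings.
// rings: list of Nx2 numeric matrices (closed implicitly).
// ---------------------------------------------------------------------------

static bool on_segment(double px, double py, double ax, double ay,
                       double bx, double by, double tol) {
  double abx = bx - ax, aby = by - ay;
  double apx = px - ax, apy = py - ay;
  double cross = abx * apy - aby * apx;
  double len = std::sqrt(abx * abx + aby * aby);
  if (len == 0)
    return std::sqrt(apx * apx + apy * apy) <= tol;
  if (std::fabs(cross) / len > tol) return false;
  double dot = apx * abx + apy * aby;
  return dot >= -tol * len && dot <= len * len + tol * len;
}

// [[Rcpp::export]]
LogicalVector pip_impl(NumericVector px, NumericVector py, List rings,
                       double tol) {
  int n = px.size();
  LogicalVector out(n);
  int nr = rings.size();
  std::vector<NumericMatrix> R(nr);
  for (int r = 0; r < nr; ++r) R[r] = as<NumericMatrix>(rings[r]);
  for (int i = 0; i < n; ++i) {
    double qx = px[i], qy = py[i];
    bool inside = false, boundary = false;
    for (int r = 0; r < nr && !boundary; ++r) {
      const NumericMatrix& P = R[r];
      int m = P.nrow();
      for (int j = 0, k = m - 1; j < m; k = j++) {
        double ax = P(k, 0), ay = P(k, 1), bx = P(j, 0), by = P(j, 1);
        if (on_segment(qx, qy, ax, ay, bx, by, tol)) { boundary = true; break; }
        if (((ay > qy) != (by > qy)) &&
            (qx < (bx - ax) * (qy - ay) / (by - ay) + ax))
          inside = !inside;
      }
    }
    out[i] = boundary || inside;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Radial pair counting.
// ---------------------------------------------------------------------------

static int bin_of(double d, const NumericVector& edges) {
  // half-open bins [e_k, e_{k+1}); -1 if outside
  int nb = edges.size() - 1;
  if (d < edges[0] || d >= edges[nb]) return -1;
  int lo = 0, hi = nb;  // invariant edges[lo] <= d < edges[hi]
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (d >= edges[mid]) lo = mid; else hi = mid;
  }
  return lo;
}

// unordered pairs (i < j) of one point set, histogrammed by distance
// [[Rcpp::export]]
NumericVector pair_hist_auto(NumericVector x, NumericVector y,
                             NumericVector edges) {
  int n = x.size(), nb = edges.size() - 1;
  NumericVector counts(nb);
  double rmax = edges[nb];
  double rmax2 = rmax * rmax;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d2 = dx * dx + dy * dy;
      if (d2 >= rmax2) continue;
      int b = bin_of(std::sqrt(d2), edges);
      if (b >= 0) counts[b] += 1;
    }
  }
  return counts;
}

// per-center histogram of distances to a second point set
// [[Rcpp::export]]
NumericMatrix pair_hist_cross(NumericVector cx, NumericVector cy,
                              NumericVector px, NumericVector py,
                              NumericVector edges) {
  int nc = cx.size(), np = px.size(), nb = edges.size() - 1;
  NumericMatrix counts(nc, nb);
  for (int i = 0; i < nc; ++i) {
    for (int j = 0; j < np; ++j) {
      double dx = cx[i] - px[j], dy = cy[i] - py[j];
      int b = bin_of(std::sqrt(dx * dx + dy * dy), edges);
      if (b >= 0) counts(i, b) += 1;
    }
  }
  return counts;
}

// ---------------------------------------------------------------------------
// Per-center annulus \cap ROI areas from a rasterized ROI mask.
// mask: logical matrix, mask(ix, iy) covering cell center
//   (ox + (ix+0.5)*cell, oy + (iy+0.5)*cell), 0-based ix rows.
// Returns centers x bins matrix of areas (same units^2 as cell).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix annulus_area_impl(LogicalMatrix mask, double cell,
                                double ox, double oy,
                                NumericVector cx, NumericVector cy,
                                NumericVector edges) {
  int nx = mask.nrow(), ny = mask.ncol();
  int nc = cx.size(), nb = edges.size() - 1;
  NumericMatrix area(nc, nb);
  double ca = cell * cell;
  for (int ix = 0; ix < nx; ++ix) {
    double wx = ox + (ix + 0.5) * cell;
    for (int iy = 0; iy < ny; ++iy) {
      if (!mask(ix, iy)) continue;
      double wy = oy + (iy + 0.5) * cell;
      for (int i = 0; i < nc; ++i) {
        double dx = wx - cx[i], dy = wy - cy[i];
        int b = bin_of(std::sqrt(dx * dx + dy * dy), edges);
        if (b >= 0) area(i, b) += ca;
      }
    }
  }
  return area;
}

// ---------------------------------------------------------------------------
// Averaged shifted histogram on a pixel grid. Each localization lands in its
// containing pixel and spreads a separable triangular kernel over the
// (2m-1)^2 neighborhood; kernel weights sum to exactly 1 per point, so total
// mass equals the number of points (the grid includes an m-1 pixel margin).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix ash_impl(NumericVector x, NumericVector y, double ox, double oy,
                       double pixel, int m, int nx, int ny) {
  NumericMatrix img(nx, ny);
  int n = x.size();
  double inv_m2 = 1.0 / ((double)m * m);
  for (int i = 0; i < n; ++i) {
    int bx = (int)std::floor((x[i] - ox) / pixel);
    int by = (int)std::floor((y[i] - oy) / pixel);
    for (int dx = -(m - 1); dx <= m - 1; ++dx) {
      int gx = bx + dx;
      if (gx < 0 || gx >= nx) continue;
      double wx = 1.0 - std::fabs((double)dx) / m;
      for (int dy = -(m - 1); dy <= m - 1; ++dy) {
        int gy = by + dy;
        if (gy < 0 || gy >= ny) continue;
        double wy = 1.0 - std::fabs((double)dy) / m;
        img(gx, gy) += wx * wy * inv_m2;
      }
    }
  }
  return img;
}
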