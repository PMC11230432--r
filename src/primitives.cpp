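// Low-level numeric primitives: dense linear assignment (shortest augmenting
// paths with potentials), incremental Bowyer-Watson Delaunay triangulation,
// connected-component labeling, and separable 2D convolution. These back the
// tracking, colony-context and colony-mask modules; each has a brute-force
// oracle in the test suite.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Linear assignment: minimise sum_i cost(i, sigma(i)) over permutations sigma
// of a square cost matrix. Classic O(n^3) shortest-augmenting-path algorithm
// with dual potentials; deterministic for a given matrix.
// Returns 1-based column assigned to each row.
// [[Rcpp::export]]
IntegerVector lap_solve(NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  if (n == 0) return IntegerVector(0);
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      const int i0 = p[j0];
      int j1 = 0;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        const double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      if (!std::isfinite(delta)) stop("assignment infeasible (no finite-cost perfect matching)");
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { const int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= n; ++j) if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}

// ---------------------------------------------------------------------------
// Delaunay triangulation (Bowyer-Watson). Input: n x 2 coordinates. Output:
// m x 2 matrix of 1-based vertex index pairs (i < j), the Delaunay edges.
namespace {
struct Tri { int a, b, c; bool alive; };

inline bool in_circumcircle(double ax, double ay, double bx, double by,
                            double cx, double cy, double px, double py) {
  // signed area orients the test; > 0 means p strictly inside
  const double orient = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
  double adx = ax - px, ady = ay - py;
  double bdx = bx - px, bdy = by - py;
  double cdx = cx - px, cdy = cy - py;
  double det =
      (adx * adx + ady * ady) * (bdx * cdy - cdx * bdy) -
      (bdx * bdx + bdy * bdy) * (adx * cdy - cdx * ady) +
      (cdx * cdx + cdy * cdy) * (adx * bdy - bdx * ady);
  if (orient < 0) det = -det;
  return det > 0;
}
} // namespace

// [[Rcpp::export]]
IntegerMatrix delaunay_edges_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 3) stop("need at least 3 points");
  // super-triangle enclosing all points by a wide margin
  double xmin = pts(0, 0), xmax = xmin, ymin = pts(0, 1), ymax = ymin;
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, pts(i, 0)); xmax = std::max(xmax, pts(i, 0));
    ymin = std::min(ymin, pts(i, 1)); ymax = std::max(ymax, pts(i, 1));
  }
  // normalize to the unit box for conditioning; super-triangle far enough
  // out that it lies outside every circumcircle of a non-degenerate real
  // triangle (margin 1e5 in unit-box units)
  const double dmax = std::max(xmax - xmin, ymax - ymin) + 1e-12;
  std::vector<double> px(n + 3), py(n + 3);
  for (int i = 0; i < n; ++i) {
    px[i] = (pts(i, 0) - xmin) / dmax;
    py[i] = (pts(i, 1) - ymin) / dmax;
  }
  const double M = 1e5;
  px[n]     = 0.5 - 2.0 * M; py[n]     = 0.5 - M;
  px[n + 1] = 0.5;           py[n + 1] = 0.5 + 2.0 * M;
  px[n + 2] = 0.5 + 2.0 * M; py[n + 2] = 0.5 - M;

  std::vector<Tri> tris;
  tris.push_back({n, n + 1, n + 2, true});

  for (int ip = 0; ip < n; ++ip) {
    const double qx = px[ip], qy = py[ip];
    std::vector<int> bad;
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!tris[t].alive) continue;
      const Tri& T = tris[t];
      if (in_circumcircle(px[T.a], py[T.a], px[T.b], py[T.b],
                          px[T.c], py[T.c], qx, qy))
        bad.push_back((int)t);
    }
    // boundary of the cavity: edges of bad triangles that appear exactly once
    std::vector<std::pair<int,int>> edges;
    for (int bt : bad) {
      const Tri& T = tris[bt];
      edges.push_back({T.a, T.b});
      edges.push_back({T.b, T.c});
      edges.push_back({T.c, T.a});
      tris[bt].alive = false;
    }
    std::vector<bool> dup(edges.size(), false);
    for (size_t e1 = 0; e1 < edges.size(); ++e1)
      for (size_t e2 = e1 + 1; e2 < edges.size(); ++e2) {
        if ((edges[e1].first == edges[e2].second &&
             edges[e1].second == edges[e2].first) ||
            (edges[e1].first == edges[e2].first &&
             edges[e1].second == edges[e2].second)) {
          dup[e1] = dup[e2] = true;
        }
      }
    for (size_t e = 0; e < edges.size(); ++e)
      if (!dup[e]) tris.push_back({edges[e].first, edges[e].second, ip, true});
  }

  std::vector<std::pair<int,int>> out;
  for (const Tri& T : tris) {
    if (!T.alive) continue;
    if (T.a >= n || T.b >= n || T.c >= n) continue;
    int v[3] = {T.a, T.b, T.c};
    for (int k = 0; k < 3; ++k) {
      int i = v[k], j = v[(k + 1) % 3];
      if (i > j) std::swap(i, j);
      out.push_back({i, j});
    }
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  IntegerMatrix em((int)out.size(), 2);
  for (size_t k = 0; k < out.size(); ++k) {
    em(k, 0) = out[k].first + 1;
    em(k, 1) = out[k].second + 1;
  }
  return em;
}

// ---------------------------------------------------------------------------
// Connected-component labeling of a logical matrix; connectivity 4 or 8.
// Returns integer matrix, 0 = background, components numbered from 1 in
// raster-scan discovery order.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        const int cur = stack.back(); stack.pop_back();
        const int cr = cur % nr, cc = cur / nr;
        for (int k = 0; k < nn; ++k) {
          const int r2 = cr + dr8[k], c2 = cc + dc8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Separable 2D convolution with replicate (edge) padding. kr is applied along
// rows (y), kc along columns (x); both must have odd length.
// [[Rcpp::export]]
NumericMatrix conv2_sep_cpp(NumericMatrix img, NumericVector kr, NumericVector kc) {
  const int nr = img.nrow(), nc = img.ncol();
  const int hr = kr.size() / 2, hc = kc.size() / 2;
  if (kr.size() % 2 == 0 || kc.size() % 2 == 0) stop("kernel lengths must be odd");
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double s = 0.0;
      for (int k = -hr; k <= hr; ++k) {
        int rr = r + k;
        if (rr < 0) rr = 0; else if (rr >= nr) rr = nr - 1;
        s += img(rr, c) * kr[k + hr];
      }
      tmp(r, c) = s;
    }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double s = 0.0;
      for (int k = -hc; k <= hc; ++k) {
        int cc = c + k;
        if (cc < 0) cc = 0; else if (cc >= nc) cc = nc - 1;
        s += tmp(r, cc) * kc[k + hc];
      }
      out(r, c) = s;
    }
  return out;
}
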