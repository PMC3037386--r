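// Core computational geometry: Bowyer-Watson Delaunay triangulation,
// point-in-polygon tests, convex clipping of triangle pairs, sparse
// overlap-map assembly, closest-point projection onto polylines and the
// Jacobi spring-analogy relaxation. Everything here is O(n^2)-ish but with
// tiny constants; meshes in this package stay below ~10^4 points.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline double orient2d(double ax, double ay, double bx, double by,
                              double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// > 0 when p lies inside the circumcircle of CCW triangle (a,b,c)
static inline double incircle(double ax, double ay, double bx, double by,
                              double cx, double cy, double px, double py) {
  const double adx = ax - px, ady = ay - py;
  const double bdx = bx - px, bdy = by - py;
  const double cdx = cx - px, cdy = cy - py;
  const double ad = adx * adx + ady * ady;
  const double bd = bdx * bdx + bdy * bdy;
  const double cd = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd - bd * cdy)
       - ady * (bdx * cd - bd * cdx)
       + ad  * (bdx * cdy - bdy * cdx);
}

struct Tri { int a, b, c; bool alive; };

// [[Rcpp::export]]
IntegerMatrix delaunay_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 3) stop("need at least 3 points");
  std::vector<double> xs(n + 3), ys(n + 3);
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    xs[i] = pts(i, 0); ys[i] = pts(i, 1);
    xmin = std::min(xmin, xs[i]); xmax = std::max(xmax, xs[i]);
    ymin = std::min(ymin, ys[i]); ymax = std::max(ymax, ys[i]);
  }
  const double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax);
  double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0) stop("degenerate point set");
  const double M = 50.0 * span;
  // super-triangle enclosing everything
  xs[n] = cx - 2.0 * M; ys[n] = cy - M;
  xs[n + 1] = cx + 2.0 * M; ys[n + 1] = cy - M;
  xs[n + 2] = cx; ys[n + 2] = cy + 2.0 * M;

  std::vector<Tri> tris;
  tris.push_back({n, n + 1, n + 2, true});

  std::vector<int> bad;
  std::vector<std::pair<int, int> > edges;
  for (int ip = 0; ip < n; ++ip) {
    const double px = xs[ip], py = ys[ip];
    bad.clear();
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!tris[t].alive) continue;
      const Tri &T = tris[t];
      if (incircle(xs[T.a], ys[T.a], xs[T.b], ys[T.b],
                   xs[T.c], ys[T.c], px, py) > 0.0)
        bad.push_back((int)t);
    }
    // cavity boundary = edges of bad triangles appearing exactly once
    edges.clear();
    for (size_t k = 0; k < bad.size(); ++k) {
      const Tri &T = tris[bad[k]];
      edges.push_back(std::make_pair(T.a, T.b));
      edges.push_back(std::make_pair(T.b, T.c));
      edges.push_back(std::make_pair(T.c, T.a));
      tris[bad[k]].alive = false;
    }
    for (size_t e = 0; e < edges.size(); ++e) {
      bool dup = false;
      for (size_t f = 0; f < edges.size(); ++f) {
        if (e == f) continue;
        if ((edges[e].first == edges[f].second &&
             edges[e].second == edges[f].first) ||
            (edges[e].first == edges[f].first &&
             edges[e].second == edges[f].second)) { dup = true; break; }
      }
      if (!dup) {
        Tri nt = {edges[e].first, edges[e].second, ip, true};
        // keep CCW
        if (orient2d(xs[nt.a], ys[nt.a], xs[nt.b], ys[nt.b],
                     xs[nt.c], ys[nt.c]) < 0.0) std::swap(nt.b, nt.c);
        tris.push_back(nt);
      }
    }
  }
  int count = 0;
  for (size_t t = 0; t < tris.size(); ++t)
    if (tris[t].alive && tris[t].a < n && tris[t].b < n && tris[t].c < n)
      ++count;
  IntegerMatrix out(count, 3);
  int r = 0;
  for (size_t t = 0; t < tris.size(); ++t) {
    if (!tris[t].alive) continue;
    const Tri &T = tris[t];
    if (T.a >= n || T.b >= n || T.c >= n) continue;
    out(r, 0) = T.a + 1; out(r, 1) = T.b + 1; out(r, 2) = T.c + 1;
    ++r;
  }
  return out;
}

// even-odd rule; points exactly on an edge count as inside (tolerantly)
// [[Rcpp::export]]
LogicalVector point_in_polygon_cpp(NumericVector px, NumericVector py,
                                   NumericVector vx, NumericVector vy) {
  const int n = px.size(), m = vx.size();
  LogicalVector inside(n);
  for (int i = 0; i < n; ++i) {
    bool in = false;
    const double x = px[i], y = py[i];
    for (int j = 0, k = m - 1; j < m; k = j++) {
      const double xj = vx[j], yj = vy[j], xk = vx[k], yk = vy[k];
      if (((yj > y) != (yk > y)) &&
          (x < (xk - xj) * (y - yj) / (yk - yj) + xj))
        in = !in;
    }
    inside[i] = in;
  }
  return inside;
}

// Sutherland-Hodgman clip of convex polygon P against half-plane left of a->b
static void clip_halfplane(std::vector<double> &pxs, std::vector<double> &pys,
                           double ax, double ay, double bx, double by) {
  std::vector<double> ox, oy;
  const size_t m = pxs.size();
  if (m == 0) return;
  for (size_t i = 0; i < m; ++i) {
    const size_t j = (i + 1) % m;
    const double s1 = orient2d(ax, ay, bx, by, pxs[i], pys[i]);
    const double s2 = orient2d(ax, ay, bx, by, pxs[j], pys[j]);
    if (s1 >= 0) { ox.push_back(pxs[i]); oy.push_back(pys[i]); }
    if ((s1 > 0 && s2 < 0) || (s1 < 0 && s2 > 0)) {
      const double t = s1 / (s1 - s2);
      ox.push_back(pxs[i] + t * (pxs[j] - pxs[i]));
      oy.push_back(pys[i] + t * (pys[j] - pys[i]));
    }
  }
  pxs.swap(ox); pys.swap(oy);
}

static double poly_area(const std::vector<double> &x,
                        const std::vector<double> &y) {
  const size_t m = x.size();
  if (m < 3) return 0.0;
  double a = 0.0;
  for (size_t i = 0; i < m; ++i) {
    const size_t j = (i + 1) % m;
    a += x[i] * y[j] - x[j] * y[i];
  }
  return 0.5 * a;
}

static double tri_overlap(double a0x, double a0y, double a1x, double a1y,
                          double a2x, double a2y,
                          double b0x, double b0y, double b1x, double b1y,
                          double b2x, double b2y) {
  // ensure clip triangle B is CCW
  if (orient2d(b0x, b0y, b1x, b1y, b2x, b2y) < 0.0) {
    std::swap(b1x, b2x); std::swap(b1y, b2y);
  }
  std::vector<double> px, py;
  px.push_back(a0x); px.push_back(a1x); px.push_back(a2x);
  py.push_back(a0y); py.push_back(a1y); py.push_back(a2y);
  if (orient2d(a0x, a0y, a1x, a1y, a2x, a2y) < 0.0) {
    std::swap(px[1], px[2]); std::swap(py[1], py[2]);
  }
  clip_halfplane(px, py, b0x, b0y, b1x, b1y);
  clip_halfplane(px, py, b1x, b1y, b2x, b2y);
  clip_halfplane(px, py, b2x, b2y, b0x, b0y);
  return std::fabs(poly_area(px, py));
}

// [[Rcpp::export]]
double tri_overlap_cpp(NumericMatrix a, NumericMatrix b) {
  return tri_overlap(a(0, 0), a(0, 1), a(1, 0), a(1, 1), a(2, 0), a(2, 1),
                     b(0, 0), b(0, 1), b(1, 0), b(1, 1), b(2, 0), b(2, 1));
}

// Sparse overlap map between two triangulations of (nearly) the same region.
// Candidate pairs via a uniform bounding-box grid over the target mesh.
// Returns triplets (i, j, w) with w = overlap area, 1-based indices.
// [[Rcpp::export]]
List overlap_map_cpp(NumericMatrix ptsA, IntegerMatrix triA,
                     NumericMatrix ptsB, IntegerMatrix triB,
                     double area_tol) {
  const int na = triA.nrow(), nb = triB.nrow();
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  std::vector<double> bx0(nb), bx1(nb), by0(nb), by1(nb);
  for (int j = 0; j < nb; ++j) {
    double x0 = R_PosInf, x1 = R_NegInf, y0 = R_PosInf, y1 = R_NegInf;
    for (int k = 0; k < 3; ++k) {
      const int v = triB(j, k) - 1;
      x0 = std::min(x0, ptsB(v, 0)); x1 = std::max(x1, ptsB(v, 0));
      y0 = std::min(y0, ptsB(v, 1)); y1 = std::max(y1, ptsB(v, 1));
    }
    bx0[j] = x0; bx1[j] = x1; by0[j] = y0; by1[j] = y1;
    xmin = std::min(xmin, x0); xmax = std::max(xmax, x1);
    ymin = std::min(ymin, y0); ymax = std::max(ymax, y1);
  }
  const int ng = std::max(1, (int)std::floor(std::sqrt((double)nb / 2.0)));
  const double gx = (xmax - xmin) / ng + 1e-300;
  const double gy = (ymax - ymin) / ng + 1e-300;
  std::vector<std::vector<int> > cells(ng * ng);
  for (int j = 0; j < nb; ++j) {
    int c0 = std::max(0, std::min(ng - 1, (int)((bx0[j] - xmin) / gx)));
    int c1 = std::max(0, std::min(ng - 1, (int)((bx1[j] - xmin) / gx)));
    int r0 = std::max(0, std::min(ng - 1, (int)((by0[j] - ymin) / gy)));
    int r1 = std::max(0, std::min(ng - 1, (int)((by1[j] - ymin) / gy)));
    for (int c = c0; c <= c1; ++c)
      for (int r = r0; r <= r1; ++r)
        cells[c * ng + r].push_back(j);
  }
  std::vector<int> ii, jj;
  std::vector<double> ww;
  std::vector<int> seen(nb, -1);
  for (int i = 0; i < na; ++i) {
    double ax[3], ay[3];
    double x0 = R_PosInf, x1 = R_NegInf, y0 = R_PosInf, y1 = R_NegInf;
    for (int k = 0; k < 3; ++k) {
      const int v = triA(i, k) - 1;
      ax[k] = ptsA(v, 0); ay[k] = ptsA(v, 1);
      x0 = std::min(x0, ax[k]); x1 = std::max(x1, ax[k]);
      y0 = std::min(y0, ay[k]); y1 = std::max(y1, ay[k]);
    }
    int c0 = std::max(0, std::min(ng - 1, (int)((x0 - xmin) / gx)));
    int c1 = std::max(0, std::min(ng - 1, (int)((x1 - xmin) / gx)));
    int r0 = std::max(0, std::min(ng - 1, (int)((y0 - ymin) / gy)));
    int r1 = std::max(0, std::min(ng - 1, (int)((y1 - ymin) / gy)));
    for (int c = c0; c <= c1; ++c) for (int r = r0; r <= r1; ++r) {
      const std::vector<int> &cell = cells[c * ng + r];
      for (size_t q = 0; q < cell.size(); ++q) {
        const int j = cell[q];
        if (seen[j] == i) continue;
        seen[j] = i;
        if (bx0[j] > x1 || bx1[j] < x0 || by0[j] > y1 || by1[j] < y0)
          continue;
        const int v0 = triB(j, 0) - 1, v1 = triB(j, 1) - 1, v2 = triB(j, 2) - 1;
        const double w = tri_overlap(ax[0], ay[0], ax[1], ay[1], ax[2], ay[2],
                                     ptsB(v0, 0), ptsB(v0, 1),
                                     ptsB(v1, 0), ptsB(v1, 1),
                                     ptsB(v2, 0), ptsB(v2, 1));
        if (w > area_tol) {
          ii.push_back(i + 1); jj.push_back(j + 1); ww.push_back(w);
        }
      }
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj),
                      _["w"] = wrap(ww));
}

// Closest-point projection of each query point onto a closed polyline.
// [[Rcpp::export]]
NumericMatrix project_polyline_cpp(NumericMatrix q, NumericMatrix poly) {
  const int n = q.nrow(), m = poly.nrow();
  NumericMatrix out(n, 3); // x, y, distance
  for (int i = 0; i < n; ++i) {
    const double px = q(i, 0), py = q(i, 1);
    double best = R_PosInf, bx = px, by = py;
    for (int j = 0; j < m; ++j) {
      const int k = (j + 1) % m;
      const double ax = poly(j, 0), ay = poly(j, 1);
      const double ux = poly(k, 0) - ax, uy = poly(k, 1) - ay;
      const double L2 = ux * ux + uy * uy;
      double t = L2 > 0 ? ((px - ax) * ux + (py - ay) * uy) / L2 : 0.0;
      t = std::max(0.0, std::min(1.0, t));
      const double cx = ax + t * ux, cy = ay + t * uy;
      const double d2 = (px - cx) * (px - cx) + (py - cy) * (py - cy);
      if (d2 < best) { best = d2; bx = cx; by = cy; }
    }
    out(i, 0) = bx; out(i, 1) = by; out(i, 2) = std::sqrt(best);
  }
  return out;
}

// Jacobi relaxation of the edge spring analogy: free nodes move to the
// stiffness-weighted average of their neighbors, boundary nodes are held at
// prescribed displacements. Returns displacements, iterations used and the
// final maximum update.
// [[Rcpp::export]]
List spring_jacobi_cpp(int n, IntegerMatrix edges, NumericVector k,
                       LogicalVector fixed, NumericMatrix fixed_disp,
                       int max_iter, double tol, double omega) {
  const int m = edges.nrow();
  std::vector<double> dx(n, 0.0), dy(n, 0.0), nx(n), ny(n), wsum(n);
  for (int i = 0; i < n; ++i)
    if (fixed[i]) { dx[i] = fixed_disp(i, 0); dy[i] = fixed_disp(i, 1); }
  double resid = R_PosInf;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    std::fill(nx.begin(), nx.end(), 0.0);
    std::fill(ny.begin(), ny.end(), 0.0);
    std::fill(wsum.begin(), wsum.end(), 0.0);
    for (int e = 0; e < m; ++e) {
      const int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
      const double ke = k[e];
      nx[a] += ke * dx[b]; ny[a] += ke * dy[b]; wsum[a] += ke;
      nx[b] += ke * dx[a]; ny[b] += ke * dy[a]; wsum[b] += ke;
    }
    resid = 0.0;
    for (int i = 0; i < n; ++i) {
      if (fixed[i] || wsum[i] <= 0) continue;
      const double tx = nx[i] / wsum[i], ty = ny[i] / wsum[i];
      const double ux = dx[i] + omega * (tx - dx[i]);
      const double uy = dy[i] + omega * (ty - dy[i]);
      resid = std::max(resid, std::fabs(ux - dx[i]));
      resid = std::max(resid, std::fabs(uy - dy[i]));
      dx[i] = ux; dy[i] = uy;
    }
    if (resid < tol) { ++it; break; }
  }
  NumericMatrix disp(n, 2);
  for (int i = 0; i < n; ++i) { disp(i, 0) = dx[i]; disp(i, 1) = dy[i]; }
  return List::create(_["disp"] = disp, _["iterations"] = it,
                      _["residual"] = resid);
}

// Minimum distance from each query point to a closed polyline (helper for
// interior point seeding).
// [[Rcpp::export]]
NumericVector dist_polyline_cpp(NumericMatrix q, NumericMatrix poly) {
  NumericMatrix pr = project_polyline_cpp(q, poly);
  const int n = q.nrow();
  NumericVector d(n);
  for (int i = 0; i < n; ++i) d[i] = pr(i, 2);
  return d;
}
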