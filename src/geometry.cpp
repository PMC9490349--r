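// Geometry kernels: fixed-radius neighbourhood queries on a uniform grid,
// local plane fits, connected components, 3D quickhull and point-to-mesh
// distances. All distances in the units of the input coordinates (mm).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <functional>
#include <array>
#include <iterator>
using namespace Rcpp;

namespace {

// uniform 2D bin grid over (x, y)
struct Grid2 {
  double x0, y0, cell;
  int nx, ny;
  std::vector<std::vector<int>> bins;

  Grid2(const NumericMatrix& xy, double cell_) : cell(cell_) {
    int n = xy.nrow();
    double xmin = R_PosInf, ymin = R_PosInf, xmax = R_NegInf, ymax = R_NegInf;
    for (int i = 0; i < n; ++i) {
      xmin = std::min(xmin, xy(i, 0)); xmax = std::max(xmax, xy(i, 0));
      ymin = std::min(ymin, xy(i, 1)); ymax = std::max(ymax, xy(i, 1));
    }
    x0 = xmin; y0 = ymin;
    nx = std::max(1, (int)std::floor((xmax - x0) / cell) + 1);
    ny = std::max(1, (int)std::floor((ymax - y0) / cell) + 1);
    bins.resize((size_t)nx * ny);
    for (int i = 0; i < n; ++i) bins[idx(xy(i, 0), xy(i, 1))].push_back(i);
  }
  int cx(double x) const {
    int c = (int)std::floor((x - x0) / cell);
    return std::min(std::max(c, 0), nx - 1);
  }
  int cy(double y) const {
    int c = (int)std::floor((y - y0) / cell);
    return std::min(std::max(c, 0), ny - 1);
  }
  size_t idx(double x, double y) const { return (size_t)cy(y) * nx + cx(x); }
};

// symmetric 3x3 eigen-decomposition by cyclic Jacobi; eigenvalues ascending
void eig3(double a[3][3], double val[3], double vec[3][3]) {
  double v[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  double m[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) m[i][j] = a[i][j];
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off = std::fabs(m[0][1]) + std::fabs(m[0][2]) + std::fabs(m[1][2]);
    if (off < 1e-15) break;
    for (int p = 0; p < 2; ++p) for (int q = p + 1; q < 3; ++q) {
      if (std::fabs(m[p][q]) < 1e-18) continue;
      double theta = (m[q][q] - m[p][p]) / (2.0 * m[p][q]);
      double t = (theta >= 0 ? 1.0 : -1.0) /
                 (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
      double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
      for (int k = 0; k < 3; ++k) {
        double mkp = m[k][p], mkq = m[k][q];
        m[k][p] = c * mkp - s * mkq;
        m[k][q] = s * mkp + c * mkq;
      }
      for (int k = 0; k < 3; ++k) {
        double mpk = m[p][k], mqk = m[q][k];
        m[p][k] = c * mpk - s * mqk;
        m[q][k] = s * mpk + c * mqk;
      }
      for (int k = 0; k < 3; ++k) {
        double vkp = v[k][p], vkq = v[k][q];
        v[k][p] = c * vkp - s * vkq;
        v[k][q] = s * vkp + c * vkq;
      }
    }
  }
  int ord[3] = {0, 1, 2};
  double ev[3] = {m[0][0], m[1][1], m[2][2]};
  std::sort(ord, ord + 3, [&](int i, int j) { return ev[i] < ev[j]; });
  for (int k = 0; k < 3; ++k) {
    val[k] = ev[ord[k]];
    for (int r = 0; r < 3; ++r) vec[r][k] = v[r][ord[k]];
  }
}

} // namespace

// Mean neighbourhood elevation within a planimetric radius (self excluded).
// Returns the per-point neighbour count and the neighbourhood mean of z;
// mean is NA where the count falls below min_neighbours.
// [[Rcpp::export]]
List cpp_disc_mean(NumericMatrix xy, NumericVector z, double radius,
                   int min_neighbours) {
  int n = xy.nrow();
  NumericVector mean_z(n, NA_REAL);
  IntegerVector cnt(n);
  if (n == 0) return List::create(_["mean_z"] = mean_z, _["n"] = cnt);
  double cell = std::max(radius / 2.0, 1e-9);
  Grid2 g(xy, cell);
  int reach = (int)std::ceil(radius / cell);
  double r2 = radius * radius;
  std::vector<double> px(n), py(n), pz(n);
  for (int i = 0; i < n; ++i) { px[i] = xy(i, 0); py[i] = xy(i, 1); pz[i] = z[i]; }
  for (int i = 0; i < n; ++i) {
    double xi = px[i], yi = py[i];
    int cxi = g.cx(xi), cyi = g.cy(yi);
    int cx0 = std::max(cxi - reach, 0), cx1 = std::min(cxi + reach, g.nx - 1);
    int cy0 = std::max(cyi - reach, 0), cy1 = std::min(cyi + reach, g.ny - 1);
    double s = 0.0; int k = 0;
    for (int cy = cy0; cy <= cy1; ++cy) for (int cx = cx0; cx <= cx1; ++cx) {
      const std::vector<int>& b = g.bins[(size_t)cy * g.nx + cx];
      for (int j : b) {
        double dx = px[j] - xi, dy = py[j] - yi;
        if (dx * dx + dy * dy <= r2 && j != i) { s += pz[j]; ++k; }
      }
    }
    cnt[i] = k;
    if (k >= min_neighbours) mean_z[i] = s / k;
  }
  return List::create(_["mean_z"] = mean_z, _["n"] = cnt);
}

// Local least-squares plane fit within a 3D radius (self included).
// Per point: neighbour count (incl. self), slope of the fitted plane
// (rise/run, i.e. tan of the dip angle), the absolute distance of the
// point from its fitted plane, and the unit normal. NA where count
// < min_points.
// [[Rcpp::export]]
List cpp_local_plane(NumericMatrix pts, double radius, int min_points) {
  int n = pts.nrow();
  NumericVector slope(n, NA_REAL), dist(n, NA_REAL);
  NumericMatrix normal(n, 3);
  std::fill(normal.begin(), normal.end(), NA_REAL);
  IntegerVector cnt(n);
  if (n == 0)
    return List::create(_["n"] = cnt, _["slope"] = slope, _["dist"] = dist,
                        _["normal"] = normal);
  NumericMatrix xy(n, 2);
  for (int i = 0; i < n; ++i) { xy(i, 0) = pts(i, 0); xy(i, 1) = pts(i, 1); }
  Grid2 g(xy, std::max(radius, 1e-9));
  double r2 = radius * radius;
  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
    int cx0 = std::max(g.cx(xi) - 1, 0), cx1 = std::min(g.cx(xi) + 1, g.nx - 1);
    int cy0 = std::max(g.cy(yi) - 1, 0), cy1 = std::min(g.cy(yi) + 1, g.ny - 1);
    nbr.clear();
    for (int cy = cy0; cy <= cy1; ++cy) for (int cx = cx0; cx <= cx1; ++cx) {
      const std::vector<int>& b = g.bins[(size_t)cy * g.nx + cx];
      for (int j : b) {
        double dx = pts(j, 0) - xi, dy = pts(j, 1) - yi, dz = pts(j, 2) - zi;
        if (dx * dx + dy * dy + dz * dz <= r2) nbr.push_back(j);
      }
    }
    int k = (int)nbr.size();
    cnt[i] = k;
    if (k < min_points || k < 3) continue;
    double mx = 0, my = 0, mz = 0;
    for (int j : nbr) { mx += pts(j, 0); my += pts(j, 1); mz += pts(j, 2); }
    mx /= k; my /= k; mz /= k;
    double c[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    for (int j : nbr) {
      double d0 = pts(j, 0) - mx, d1 = pts(j, 1) - my, d2 = pts(j, 2) - mz;
      c[0][0] += d0 * d0; c[0][1] += d0 * d1; c[0][2] += d0 * d2;
      c[1][1] += d1 * d1; c[1][2] += d1 * d2; c[2][2] += d2 * d2;
    }
    c[1][0] = c[0][1]; c[2][0] = c[0][2]; c[2][1] = c[1][2];
    double val[3], vec[3][3];
    eig3(c, val, vec);
    double nx = vec[0][0], ny = vec[1][0], nz = vec[2][0]; // smallest eigval
    double hor = std::sqrt(nx * nx + ny * ny);
    slope[i] = (std::fabs(nz) < 1e-300) ? R_PosInf : hor / std::fabs(nz);
    dist[i] = std::fabs((xi - mx) * nx + (yi - my) * ny + (zi - mz) * nz);
    normal(i, 0) = nx; normal(i, 1) = ny; normal(i, 2) = nz;
  }
  return List::create(_["n"] = cnt, _["slope"] = slope, _["dist"] = dist,
                      _["normal"] = normal);
}

// 3D nearest-neighbour distance per point. Points are binned planimetrically;
// ring expansion is valid because the 3D distance is bounded below by the
// planimetric distance.
// [[Rcpp::export]]
NumericVector cpp_nn_dist3(NumericMatrix pts) {
  int n = pts.nrow();
  NumericVector out(n, NA_REAL);
  if (n < 2) return out;
  NumericMatrix xy(n, 2);
  for (int i = 0; i < n; ++i) { xy(i, 0) = pts(i, 0); xy(i, 1) = pts(i, 1); }
  double xmin = R_PosInf, ymin = R_PosInf, xmax = R_NegInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    xmin = std::min(xmin, xy(i, 0)); xmax = std::max(xmax, xy(i, 0));
    ymin = std::min(ymin, xy(i, 1)); ymax = std::max(ymax, xy(i, 1));
  }
  double span = std::max(xmax - xmin, ymax - ymin);
  double cell = std::max(span / std::sqrt((double)n), span * 1e-12);
  if (cell <= 0) cell = 1.0;
  Grid2 g(xy, cell);
  for (int i = 0; i < n; ++i) {
    double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
    int ci = g.cx(xi), cj = g.cy(yi);
    double best = R_PosInf;
    int maxring = std::max(g.nx, g.ny);
    for (int ring = 0; ring <= maxring; ++ring) {
      if (best < R_PosInf && (double)(ring - 1) * cell > std::sqrt(best)) break;
      int cx0 = std::max(ci - ring, 0), cx1 = std::min(ci + ring, g.nx - 1);
      int cy0 = std::max(cj - ring, 0), cy1 = std::min(cj + ring, g.ny - 1);
      for (int cy = cy0; cy <= cy1; ++cy) for (int cx = cx0; cx <= cx1; ++cx) {
        if (ring > 0 && cx > cx0 && cx < cx1 && cy > cy0 && cy < cy1) continue;
        for (int j : g.bins[(size_t)cy * g.nx + cx]) {
          if (j == i) continue;
          double dx = pts(j, 0) - xi, dy = pts(j, 1) - yi,
                 dz = pts(j, 2) - zi;
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < best) best = d2;
        }
      }
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

namespace {

struct DTri {
  int v[3];   // vertex indices (CCW)
  int adj[3]; // adj[i] = triangle across edge opposite v[i], -1 if none
  bool alive = true;
};

inline double orient2(double ax, double ay, double bx, double by, double cx,
                      double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// > 0 iff d lies inside the circumcircle of CCW triangle (a, b, c)
inline double incircle(double ax, double ay, double bx, double by, double cx,
                       double cy, double dx, double dy) {
  double adx = ax - dx, ady = ay - dy;
  double bdx = bx - dx, bdy = by - dy;
  double cdx = cx - dx, cdy = cy - dy;
  double ad = adx * adx + ady * ady;
  double bd = bdx * bdx + bdy * bdy;
  double cd = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd - bd * cdy) - ady * (bdx * cd - bd * cdx) +
         ad * (bdx * cdy - bdy * cdx);
}

} // namespace

// Delaunay triangulation of a planar point set (Bowyer-Watson with walk
// location; points are inserted in a spatially coherent order). Returns
// 1-based triangle vertex indices. Duplicate points must be removed by the
// caller; collinear inputs yield zero triangles.
// [[Rcpp::export]]
IntegerMatrix cpp_delaunay(NumericMatrix xy) {
  int n = xy.nrow();
  if (n < 3) return IntegerMatrix(0, 3);
  std::vector<double> px(n), py(n);
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    px[i] = xy(i, 0); py[i] = xy(i, 1);
    xmin = std::min(xmin, px[i]); xmax = std::max(xmax, px[i]);
    ymin = std::min(ymin, py[i]); ymax = std::max(ymax, py[i]);
  }
  double cx0 = (xmin + xmax) / 2, cy0 = (ymin + ymax) / 2;
  double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0) return IntegerMatrix(0, 3);
  for (int i = 0; i < n; ++i) { px[i] -= cx0; py[i] -= cy0; }

  // insertion order: serpentine over grid cells for walk locality
  double cell = span / std::max(1.0, std::sqrt((double)n));
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  int ncols = std::max(1, (int)(span / cell) + 1);
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    int ra = (int)((py[a] - (ymin - cy0)) / cell);
    int rb = (int)((py[b] - (ymin - cy0)) / cell);
    if (ra != rb) return ra < rb;
    double xa = (ra % 2 == 0) ? px[a] : -px[a];
    double xb = (rb % 2 == 0) ? px[b] : -px[b];
    return xa < xb;
  });
  (void)ncols;

  // super-triangle
  double M = 64.0 * span;
  px.push_back(-M); py.push_back(-M);      // n
  px.push_back(M);  py.push_back(-M);      // n + 1
  px.push_back(0);  py.push_back(M);       // n + 2

  std::vector<DTri> tris;
  tris.reserve(2 * n + 16);
  tris.push_back({{n, n + 1, n + 2}, {-1, -1, -1}, true});
  int last = 0;

  std::vector<int> cavity, bstack;
  std::vector<int> stamp;
  stamp.reserve(2 * n + 16);
  int cur = 0;
  double scan_tol = 1e-9 * span * span;

  for (int oi = 0; oi < n; ++oi) {
    int p = order[oi];
    ++cur;
    stamp.resize(tris.size(), 0);
    double pxx = px[p], pyy = py[p];
    // locate by walking
    int t = last;
    if (!tris[t].alive) {
      t = -1;
      for (int k = (int)tris.size() - 1; k >= 0; --k)
        if (tris[k].alive) { t = k; break; }
    }
    int guard = 0, maxguard = 8 * (int)tris.size() + 64;
    while (true) {
      if (++guard > maxguard) { t = -1; break; }
      const DTri& tr = tris[t];
      int moved = -1;
      for (int e = 0; e < 3; ++e) {
        int a = tr.v[(e + 1) % 3], b = tr.v[(e + 2) % 3];
        if (orient2(px[a], py[a], px[b], py[b], pxx, pyy) < 0) {
          if (tr.adj[e] >= 0) { moved = tr.adj[e]; break; }
        }
      }
      if (moved < 0) break;
      t = moved;
    }
    if (t < 0) { // numerical fallback: scan
      for (int k = 0; k < (int)tris.size(); ++k) {
        if (!tris[k].alive) continue;
        const DTri& tr = tris[k];
        bool inside = true;
        for (int e = 0; e < 3 && inside; ++e) {
          int a = tr.v[(e + 1) % 3], b = tr.v[(e + 2) % 3];
          if (orient2(px[a], py[a], px[b], py[b], pxx, pyy) < -scan_tol)
            inside = false;
        }
        if (inside) { t = k; break; }
      }
      if (t < 0) stop("Delaunay point location failed");
    }

    // cavity of triangles whose circumcircle contains p (BFS)
    cavity.clear();
    bstack.clear();
    bstack.push_back(t);
    stamp[t] = cur;
    while (!bstack.empty()) {
      int k = bstack.back(); bstack.pop_back();
      cavity.push_back(k);
      const DTri tr = tris[k];
      for (int e = 0; e < 3; ++e) {
        int nb = tr.adj[e];
        if (nb < 0 || stamp[nb] == cur || !tris[nb].alive) continue;
        const DTri& nt = tris[nb];
        if (incircle(px[nt.v[0]], py[nt.v[0]], px[nt.v[1]], py[nt.v[1]],
                     px[nt.v[2]], py[nt.v[2]], pxx, pyy) > 0) {
          stamp[nb] = cur;
          bstack.push_back(nb);
        }
      }
    }

    // boundary edges of the cavity
    struct BEdge { int a, b, outside; };
    std::vector<BEdge> bedges;
    for (int k : cavity) {
      const DTri& tr = tris[k];
      for (int e = 0; e < 3; ++e) {
        int nb = tr.adj[e];
        if (nb >= 0 && stamp[nb] == cur) continue;
        bedges.push_back({tr.v[(e + 1) % 3], tr.v[(e + 2) % 3], nb});
      }
    }
    for (int k : cavity) tris[k].alive = false;

    // fan of new triangles; link adjacencies
    std::vector<int> fresh(bedges.size());
    for (size_t j = 0; j < bedges.size(); ++j) {
      DTri nt;
      nt.v[0] = p; nt.v[1] = bedges[j].a; nt.v[2] = bedges[j].b;
      nt.adj[0] = bedges[j].outside; // edge (a, b) faces the outside tri
      nt.adj[1] = -1; nt.adj[2] = -1;
      tris.push_back(nt);
      fresh[j] = (int)tris.size() - 1;
      int out = bedges[j].outside;
      if (out >= 0) {
        // relink the outside triangle across its edge equal to (a, b)
        for (int e = 0; e < 3; ++e) {
          int oa = tris[out].v[(e + 1) % 3], ob = tris[out].v[(e + 2) % 3];
          if ((oa == bedges[j].a && ob == bedges[j].b) ||
              (oa == bedges[j].b && ob == bedges[j].a)) {
            tris[out].adj[e] = fresh[j];
            break;
          }
        }
      }
    }
    // internal adjacency: new triangle j has edges (p, a) and (p, b);
    // match b of one with a of another
    std::vector<std::pair<int, int>> byA(bedges.size());
    for (size_t j = 0; j < bedges.size(); ++j)
      byA[j] = {bedges[j].a, (int)j};
    std::sort(byA.begin(), byA.end());
    for (size_t j = 0; j < bedges.size(); ++j) {
      // edge (p, b) of triangle j (opposite vertex a, local index 1)
      int b = bedges[j].b;
      auto it = std::lower_bound(byA.begin(), byA.end(),
                                 std::make_pair(b, -1));
      if (it != byA.end() && it->first == b) {
        int j2 = it->second;
        tris[fresh[j]].adj[1] = fresh[j2];  // across edge (p, b)
        tris[fresh[j2]].adj[2] = fresh[j];  // across edge (p, a) of j2
      }
    }
    last = fresh.empty() ? last : fresh[0];
  }

  int m = 0;
  for (const DTri& tr : tris)
    if (tr.alive && tr.v[0] < n && tr.v[1] < n && tr.v[2] < n) ++m;
  IntegerMatrix out(m, 3);
  int r = 0;
  for (const DTri& tr : tris) {
    if (!(tr.alive && tr.v[0] < n && tr.v[1] < n && tr.v[2] < n)) continue;
    // normalise: smallest vertex first, keep CCW order
    int a = tr.v[0], b = tr.v[1], c = tr.v[2];
    if (b <= a && b <= c) { int t0 = a; a = b; b = c; c = t0; }
    else if (c <= a && c <= b) { int t0 = c; c = b; b = a; a = t0; }
    out(r, 0) = a + 1; out(r, 1) = b + 1; out(r, 2) = c + 1;
    ++r;
  }
  return out;
}

// Reconstruct Delaunay triangles from the Delaunay edge list (deldir's
// delsgs). For each edge the face-completing vertex on each side is the
// common neighbour subtending the maximal angle over that edge (empty
// circumcircle property). edges are 1-based; returns 1-based triangles.
// [[Rcpp::export]]
IntegerMatrix cpp_delaunay_faces(IntegerMatrix edges, NumericMatrix xy) {
  int n = xy.nrow(), m = edges.nrow();
  std::vector<std::vector<int>> adj(n);
  for (int e = 0; e < m; ++e) {
    int i = edges(e, 0) - 1, j = edges(e, 1) - 1;
    adj[i].push_back(j);
    adj[j].push_back(i);
  }
  for (int i = 0; i < n; ++i) std::sort(adj[i].begin(), adj[i].end());
  std::vector<std::array<int, 3>> tris;
  std::vector<int> common;
  for (int e = 0; e < m; ++e) {
    int i = edges(e, 0) - 1, j = edges(e, 1) - 1;
    if (i > j) std::swap(i, j);
    common.clear();
    std::set_intersection(adj[i].begin(), adj[i].end(), adj[j].begin(),
                          adj[j].end(), std::back_inserter(common));
    double ex = xy(j, 0) - xy(i, 0), ey = xy(j, 1) - xy(i, 1);
    int best_k[2] = {-1, -1};
    double best_cos[2] = {2.0, 2.0}; // smaller cos == larger angle
    for (int k : common) {
      double ux = xy(i, 0) - xy(k, 0), uy = xy(i, 1) - xy(k, 1);
      double vx = xy(j, 0) - xy(k, 0), vy = xy(j, 1) - xy(k, 1);
      double cross = ex * (xy(k, 1) - xy(i, 1)) - ey * (xy(k, 0) - xy(i, 0));
      int side = cross > 0 ? 0 : 1;
      double ca = (ux * vx + uy * vy) /
                  std::sqrt((ux * ux + uy * uy) * (vx * vx + vy * vy));
      if (ca < best_cos[side]) { best_cos[side] = ca; best_k[side] = k; }
    }
    for (int s = 0; s < 2; ++s) {
      if (best_k[s] < 0) continue;
      std::array<int, 3> t = {i, j, best_k[s]};
      std::sort(t.begin(), t.end());
      tris.push_back(t);
    }
  }
  std::sort(tris.begin(), tris.end());
  tris.erase(std::unique(tris.begin(), tris.end()), tris.end());
  IntegerMatrix out((int)tris.size(), 3);
  for (size_t r = 0; r < tris.size(); ++r)
    for (int c = 0; c < 3; ++c) out((int)r, c) = tris[r][c] + 1;
  return out;
}

// Connected components under planimetric radius linkage (union-find).
// Returns 1-based component labels, renumbered in order of first appearance.
// [[Rcpp::export]]
IntegerVector cpp_link_components(NumericMatrix xy, double radius) {
  int n = xy.nrow();
  IntegerVector lab(n);
  if (n == 0) return lab;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  Grid2 g(xy, std::max(radius, 1e-9));
  double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    double xi = xy(i, 0), yi = xy(i, 1);
    int cx0 = std::max(g.cx(xi) - 1, 0), cx1 = std::min(g.cx(xi) + 1, g.nx - 1);
    int cy0 = std::max(g.cy(yi) - 1, 0), cy1 = std::min(g.cy(yi) + 1, g.ny - 1);
    for (int cy = cy0; cy <= cy1; ++cy) for (int cx = cx0; cx <= cx1; ++cx) {
      const std::vector<int>& b = g.bins[(size_t)cy * g.nx + cx];
      for (int j : b) {
        if (j <= i) continue;
        double dx = xy(j, 0) - xi, dy = xy(j, 1) - yi;
        if (dx * dx + dy * dy <= r2) {
          int ri = find(i), rj = find(j);
          if (ri != rj) parent[rj] = ri;
        }
      }
    }
  }
  std::vector<int> renum(n, 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    if (renum[r] == 0) renum[r] = ++next;
    lab[i] = renum[r];
  }
  return lab;
}

// Planimetric nearest-neighbour distance per point (ring-expanding search).
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericMatrix xy) {
  int n = xy.nrow();
  NumericVector out(n, NA_REAL);
  if (n < 2) return out;
  double xmin = R_PosInf, ymin = R_PosInf, xmax = R_NegInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    xmin = std::min(xmin, xy(i, 0)); xmax = std::max(xmax, xy(i, 0));
    ymin = std::min(ymin, xy(i, 1)); ymax = std::max(ymax, xy(i, 1));
  }
  double span = std::max(xmax - xmin, ymax - ymin);
  double cell = std::max(span / std::sqrt((double)n), span * 1e-12);
  if (cell <= 0) cell = 1.0;
  Grid2 g(xy, cell);
  for (int i = 0; i < n; ++i) {
    double xi = xy(i, 0), yi = xy(i, 1);
    int ci = g.cx(xi), cj = g.cy(yi);
    double best = R_PosInf;
    int maxring = std::max(g.nx, g.ny);
    for (int ring = 0; ring <= maxring; ++ring) {
      // once a candidate is found, one extra ring guarantees correctness
      if (best < R_PosInf && (double)(ring - 1) * cell > std::sqrt(best)) break;
      int cx0 = std::max(ci - ring, 0), cx1 = std::min(ci + ring, g.nx - 1);
      int cy0 = std::max(cj - ring, 0), cy1 = std::min(cj + ring, g.ny - 1);
      for (int cy = cy0; cy <= cy1; ++cy) for (int cx = cx0; cx <= cx1; ++cx) {
        if (ring > 0 && cx > cx0 && cx < cx1 && cy > cy0 && cy < cy1) continue;
        for (int j : g.bins[(size_t)cy * g.nx + cx]) {
          if (j == i) continue;
          double dx = xy(j, 0) - xi, dy = xy(j, 1) - yi;
          double d2 = dx * dx + dy * dy;
          if (d2 < best) best = d2;
        }
      }
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

namespace {

struct Face {
  int a, b, c;              // 0-based vertex indices
  double nx, ny, nz, off;   // outward unit normal, plane offset (n . x = off)
  std::vector<int> outside; // candidate points strictly outside
  bool alive = true;
};

inline void face_plane(Face& f, const NumericMatrix& p) {
  double ux = p(f.b, 0) - p(f.a, 0), uy = p(f.b, 1) - p(f.a, 1),
         uz = p(f.b, 2) - p(f.a, 2);
  double vx = p(f.c, 0) - p(f.a, 0), vy = p(f.c, 1) - p(f.a, 1),
         vz = p(f.c, 2) - p(f.a, 2);
  f.nx = uy * vz - uz * vy;
  f.ny = uz * vx - ux * vz;
  f.nz = ux * vy - uy * vx;
  double L = std::sqrt(f.nx * f.nx + f.ny * f.ny + f.nz * f.nz);
  if (L > 0) { f.nx /= L; f.ny /= L; f.nz /= L; }
  f.off = f.nx * p(f.a, 0) + f.ny * p(f.a, 1) + f.nz * p(f.a, 2);
}

inline double face_dist(const Face& f, const NumericMatrix& p, int i) {
  return f.nx * p(i, 0) + f.ny * p(i, 1) + f.nz * p(i, 2) - f.off;
}

} // namespace

// 3D convex hull (quickhull). Returns an m x 3 matrix of 1-based point
// indices; faces are wound so their normals point outward. Errors on
// degenerate (collinear/coplanar) input.
// [[Rcpp::export]]
IntegerMatrix cpp_quickhull3(NumericMatrix p) {
  int n = p.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");
  double span = 0;
  for (int d = 0; d < 3; ++d) {
    double lo = R_PosInf, hi = R_NegInf;
    for (int i = 0; i < n; ++i) { lo = std::min(lo, p(i, d)); hi = std::max(hi, p(i, d)); }
    span = std::max(span, hi - lo);
  }
  double eps = std::max(1e-12, 1e-9 * span);

  // initial simplex: farthest pair among axis extremes, then line, then plane
  int ext[6];
  for (int d = 0; d < 3; ++d) {
    int lo = 0, hi = 0;
    for (int i = 1; i < n; ++i) {
      if (p(i, d) < p(lo, d)) lo = i;
      if (p(i, d) > p(hi, d)) hi = i;
    }
    ext[2 * d] = lo; ext[2 * d + 1] = hi;
  }
  int i0 = 0, i1 = 0; double best = -1;
  for (int a = 0; a < 6; ++a) for (int b = a + 1; b < 6; ++b) {
    double dx = p(ext[a], 0) - p(ext[b], 0), dy = p(ext[a], 1) - p(ext[b], 1),
           dz = p(ext[a], 2) - p(ext[b], 2);
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 > best) { best = d2; i0 = ext[a]; i1 = ext[b]; }
  }
  if (best <= eps * eps) stop("degenerate point cloud (all points coincide)");
  double ax = p(i1, 0) - p(i0, 0), ay = p(i1, 1) - p(i0, 1), az = p(i1, 2) - p(i0, 2);
  double aL2 = ax * ax + ay * ay + az * az;
  int i2 = -1; best = eps;
  for (int i = 0; i < n; ++i) {
    double wx = p(i, 0) - p(i0, 0), wy = p(i, 1) - p(i0, 1), wz = p(i, 2) - p(i0, 2);
    double cxv = ay * wz - az * wy, cyv = az * wx - ax * wz, czv = ax * wy - ay * wx;
    double d = std::sqrt((cxv * cxv + cyv * cyv + czv * czv) / aL2);
    if (d > best) { best = d; i2 = i; }
  }
  if (i2 < 0) stop("degenerate point cloud (collinear points)");
  Face f0{i0, i1, i2};
  face_plane(f0, p);
  int i3 = -1; best = eps;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(face_dist(f0, p, i));
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0) stop("degenerate point cloud (coplanar points)");

  std::vector<Face> faces;
  double cx = (p(i0, 0) + p(i1, 0) + p(i2, 0) + p(i3, 0)) / 4.0;
  double cy = (p(i0, 1) + p(i1, 1) + p(i2, 1) + p(i3, 1)) / 4.0;
  double cz = (p(i0, 2) + p(i1, 2) + p(i2, 2) + p(i3, 2)) / 4.0;
  int tet[4][3] = {{i0, i1, i2}, {i0, i1, i3}, {i0, i2, i3}, {i1, i2, i3}};
  for (auto& t : tet) {
    Face f{t[0], t[1], t[2]};
    face_plane(f, p);
    if (f.nx * cx + f.ny * cy + f.nz * cz - f.off > 0) { // flip outward
      std::swap(f.b, f.c);
      face_plane(f, p);
    }
    faces.push_back(f);
  }
  // assign outside sets
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    for (auto& f : faces)
      if (face_dist(f, p, i) > eps) { f.outside.push_back(i); break; }
  }

  std::vector<int> work;
  for (int k = 0; k < 4; ++k) if (!faces[k].outside.empty()) work.push_back(k);

  while (!work.empty()) {
    int fi = work.back(); work.pop_back();
    if (!faces[fi].alive || faces[fi].outside.empty()) continue;
    Face& f = faces[fi];
    int far = f.outside[0]; double fd = face_dist(f, p, far);
    for (int i : f.outside) {
      double d = face_dist(f, p, i);
      if (d > fd) { fd = d; far = i; }
    }
    // visible faces
    std::vector<int> vis;
    for (size_t k = 0; k < faces.size(); ++k)
      if (faces[k].alive && face_dist(faces[k], p, far) > eps)
        vis.push_back((int)k);
    if (vis.empty()) continue;
    // horizon: directed edges of visible faces whose reverse is not visible
    std::vector<std::pair<int, int>> edges;
    for (int k : vis) {
      const Face& g = faces[k];
      edges.emplace_back(g.a, g.b);
      edges.emplace_back(g.b, g.c);
      edges.emplace_back(g.c, g.a);
    }
    std::vector<std::pair<int, int>> horizon;
    for (auto& e : edges) {
      bool internal = false;
      for (auto& e2 : edges)
        if (e2.first == e.second && e2.second == e.first) { internal = true; break; }
      if (!internal) horizon.push_back(e);
    }
    std::vector<int> orphan;
    for (int k : vis) {
      faces[k].alive = false;
      for (int i : faces[k].outside) if (i != far) orphan.push_back(i);
      faces[k].outside.clear();
    }
    std::vector<int> fresh;
    for (auto& e : horizon) {
      Face nf{e.first, e.second, far};
      face_plane(nf, p);
      if (nf.nx * cx + nf.ny * cy + nf.nz * cz - nf.off > 0) {
        std::swap(nf.b, nf.c);
        face_plane(nf, p);
      }
      faces.push_back(nf);
      fresh.push_back((int)faces.size() - 1);
    }
    for (int i : orphan) {
      for (int k : fresh)
        if (face_dist(faces[k], p, i) > eps) { faces[k].outside.push_back(i); break; }
    }
    for (int k : fresh) if (!faces[k].outside.empty()) work.push_back(k);
  }

  int m = 0;
  for (auto& f : faces) if (f.alive) ++m;
  IntegerMatrix out(m, 3);
  int r = 0;
  for (auto& f : faces) {
    if (!f.alive) continue;
    out(r, 0) = f.a + 1; out(r, 1) = f.b + 1; out(r, 2) = f.c + 1;
    ++r;
  }
  return out;
}

namespace {

// squared distance from point q to triangle (a, b, c) — Ericson, RTCD 5.1.5
double tri_dist2(const double* q, const double* a, const double* b,
                 const double* c) {
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ac[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double ap[3] = {q[0] - a[0], q[1] - a[1], q[2] - a[2]};
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  auto d2pt = [&](const double* u) {
    double v[3] = {q[0] - u[0], q[1] - u[1], q[2] - u[2]};
    return v[0] * v[0] + v[1] * v[1] + v[2] * v[2];
  };
  if (d1 <= 0 && d2 <= 0) return d2pt(a);
  double bp[3] = {q[0] - b[0], q[1] - b[1], q[2] - b[2]};
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0 && d4 <= d3) return d2pt(b);
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double t = d1 / (d1 - d3);
    double pr[3] = {a[0] + t * ab[0], a[1] + t * ab[1], a[2] + t * ab[2]};
    return d2pt(pr);
  }
  double cp[3] = {q[0] - c[0], q[1] - c[1], q[2] - c[2]};
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0 && d5 <= d6) return d2pt(c);
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double t = d2 / (d2 - d6);
    double pr[3] = {a[0] + t * ac[0], a[1] + t * ac[1], a[2] + t * ac[2]};
    return d2pt(pr);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    double pr[3] = {b[0] + t * (c[0] - b[0]), b[1] + t * (c[1] - b[1]),
                    b[2] + t * (c[2] - b[2])};
    return d2pt(pr);
  }
  double denom = 1.0 / (va + vb + vc);
  double s = vb * denom, t = vc * denom;
  double pr[3] = {a[0] + s * ab[0] + t * ac[0], a[1] + s * ab[1] + t * ac[1],
                  a[2] + s * ab[2] + t * ac[2]};
  return d2pt(pr);
}

} // namespace

// Signed distance from each query point to a triangulated closed surface.
// Faces must be wound with outward normals (as from cpp_quickhull3, indices
// 1-based into vert). Negative inside, positive outside.
// [[Rcpp::export]]
NumericVector cpp_mesh_signed_dist(NumericMatrix query, NumericMatrix vert,
                                   IntegerMatrix faces) {
  int n = query.nrow(), m = faces.nrow();
  NumericVector out(n);
  // precompute face planes
  std::vector<double> nxv(m), nyv(m), nzv(m), offv(m);
  for (int k = 0; k < m; ++k) {
    int a = faces(k, 0) - 1, b = faces(k, 1) - 1, c = faces(k, 2) - 1;
    double ux = vert(b, 0) - vert(a, 0), uy = vert(b, 1) - vert(a, 1),
           uz = vert(b, 2) - vert(a, 2);
    double vx = vert(c, 0) - vert(a, 0), vy = vert(c, 1) - vert(a, 1),
           vz = vert(c, 2) - vert(a, 2);
    double nx = uy * vz - uz * vy, ny = uz * vx - ux * vz, nz = ux * vy - uy * vx;
    double L = std::sqrt(nx * nx + ny * ny + nz * nz);
    if (L > 0) { nx /= L; ny /= L; nz /= L; }
    nxv[k] = nx; nyv[k] = ny; nzv[k] = nz;
    offv[k] = nx * vert(a, 0) + ny * vert(a, 1) + nz * vert(a, 2);
  }
  for (int i = 0; i < n; ++i) {
    double q[3] = {query(i, 0), query(i, 1), query(i, 2)};
    double best = R_PosInf;
    bool inside = true;
    for (int k = 0; k < m; ++k) {
      double pd = nxv[k] * q[0] + nyv[k] * q[1] + nzv[k] * q[2] - offv[k];
      if (pd > 0) inside = false;
      if (pd * pd >= best) continue; // plane distance lower-bounds triangle distance
      int a = faces(k, 0) - 1, b = faces(k, 1) - 1, c = faces(k, 2) - 1;
      double A[3] = {vert(a, 0), vert(a, 1), vert(a, 2)};
      double B[3] = {vert(b, 0), vert(b, 1), vert(b, 2)};
      double C[3] = {vert(c, 0), vert(c, 1), vert(c, 2)};
      double d2 = tri_dist2(q, A, B, C);
      if (d2 < best) best = d2;
    }
    out[i] = (inside ? -1.0 : 1.0) * std::sqrt(best);
  }
  return out;
}
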