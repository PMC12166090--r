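// Spatial kernels: grid-bucketed nearest neighbour, fixed-radius connected
// components, point-to-polyline distance, and scanline area of a
// disk-union \ disk-union region. All distances Euclidean in the same
// (micrometre) units as the input coordinates.
#include <Rcpp.h>
#include <vector>
#include <functional>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

// Uniform grid over the bounding box of (x, y) with cell size `cell`.
struct Grid {
  double xmin, ymin, cell;
  int nx, ny;
  std::vector<std::vector<int>> buckets; // point indices per cell

  Grid(const NumericVector& x, const NumericVector& y, double cell_size) {
    int n = x.size();
    cell = cell_size;
    xmin = R_PosInf; ymin = R_PosInf;
    double xmax = R_NegInf, ymax = R_NegInf;
    for (int i = 0; i < n; ++i) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
    }
    if (n == 0) { xmin = ymin = 0.0; xmax = ymax = 0.0; }
    nx = std::max(1, (int)std::floor((xmax - xmin) / cell) + 1);
    ny = std::max(1, (int)std::floor((ymax - ymin) / cell) + 1);
    buckets.resize((size_t)nx * ny);
    for (int i = 0; i < n; ++i) buckets[index_of(x[i], y[i])].push_back(i);
  }
  inline int clampi(int v, int lo, int hi) const {
    return v < lo ? lo : (v > hi ? hi : v);
  }
  inline size_t index_of(double px, double py) const {
    int ix = clampi((int)std::floor((px - xmin) / cell), 0, nx - 1);
    int iy = clampi((int)std::floor((py - ymin) / cell), 0, ny - 1);
    return (size_t)iy * nx + ix;
  }
};

} // namespace

// For each query point, index (1-based) of and distance to the nearest
// reference point. Expanding ring search over a grid; exact.
// [[Rcpp::export(name = ".nn_lookup_cpp")]]
List nn_lookup_cpp(NumericVector qx, NumericVector qy,
                   NumericVector rx, NumericVector ry) {
  int nq = qx.size(), nr = rx.size();
  IntegerVector idx(nq, NA_INTEGER);
  NumericVector dist(nq, NA_REAL);
  if (nr == 0 || nq == 0)
    return List::create(_["index"] = idx, _["dist"] = dist);

  // heuristic cell size: aim for ~1-4 points per bucket
  double span = 1.0;
  {
    double xmn = *std::min_element(rx.begin(), rx.end());
    double xmx = *std::max_element(rx.begin(), rx.end());
    double ymn = *std::min_element(ry.begin(), ry.end());
    double ymx = *std::max_element(ry.begin(), ry.end());
    span = std::max({xmx - xmn, ymx - ymn, 1e-9});
  }
  double cell = std::max(span / std::max(1.0, std::sqrt((double)nr)), 1e-9);
  Grid g(rx, ry, cell);

  double gxmax = g.xmin + g.nx * g.cell, gymax = g.ymin + g.ny * g.cell;
  for (int q = 0; q < nq; ++q) {
    int cx = g.clampi((int)std::floor((qx[q] - g.xmin) / g.cell), 0, g.nx - 1);
    int cy = g.clampi((int)std::floor((qy[q] - g.ymin) / g.cell), 0, g.ny - 1);
    // distance from the query to the grid bounding box (0 when inside)
    double ox = std::max({g.xmin - qx[q], qx[q] - gxmax, 0.0});
    double oy = std::max({g.ymin - qy[q], qy[q] - gymax, 0.0});
    double clamp2 = ox * ox + oy * oy;
    double best = R_PosInf; int besti = -1;
    int max_ring = std::max(g.nx, g.ny);
    for (int ring = 0; ring <= max_ring; ++ring) {
      // lower bound on any point in this ring: sqrt(((ring-1)*cell)^2 + clamp^2)
      if (besti >= 0) {
        double rl = (double)(ring - 1) * g.cell;
        if (rl > 0 && rl * rl + clamp2 > best * best) break;
      }
      int x0 = cx - ring, x1 = cx + ring, y0 = cy - ring, y1 = cy + ring;
      for (int iy = y0; iy <= y1; ++iy) {
        if (iy < 0 || iy >= g.ny) continue;
        for (int ix = x0; ix <= x1; ++ix) {
          if (ix < 0 || ix >= g.nx) continue;
          // ring perimeter only
          if (ring > 0 && ix != x0 && ix != x1 && iy != y0 && iy != y1) continue;
          // prune buckets whose rectangle cannot beat the current best
          if (besti >= 0) {
            double bx0 = g.xmin + ix * g.cell, bx1 = bx0 + g.cell;
            double by0 = g.ymin + iy * g.cell, by1 = by0 + g.cell;
            double ddx = std::max({bx0 - qx[q], qx[q] - bx1, 0.0});
            double ddy = std::max({by0 - qy[q], qy[q] - by1, 0.0});
            if (ddx * ddx + ddy * ddy > best * best) continue;
          }
          const std::vector<int>& b = g.buckets[(size_t)iy * g.nx + ix];
          for (int j : b) {
            double dx = qx[q] - rx[j], dy = qy[q] - ry[j];
            double d2 = dx * dx + dy * dy;
            if (d2 < best * best || besti < 0) {
              double d = std::sqrt(d2);
              if (d < best) { best = d; besti = j; }
            }
          }
        }
      }
    }
    idx[q] = besti + 1;
    dist[q] = best;
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}

// Connected components of the graph linking points at distance <= radius.
// Union-find over grid neighbourhoods. Returns 1-based component labels
// (consecutive, ordered by first member).
// [[Rcpp::export(name = ".radius_components_cpp")]]
IntegerVector radius_components_cpp(NumericVector x, NumericVector y,
                                    double radius) {
  int n = x.size();
  IntegerVector comp(n);
  if (n == 0) return comp;
  double cell = std::max(radius, 1e-9);
  Grid g(x, y, cell);

  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };

  double r2 = radius * radius;
  for (int iy = 0; iy < g.ny; ++iy) {
    for (int ix = 0; ix < g.nx; ++ix) {
      const std::vector<int>& b = g.buckets[(size_t)iy * g.nx + ix];
      if (b.empty()) continue;
      // within-bucket pairs
      for (size_t a = 0; a < b.size(); ++a)
        for (size_t c = a + 1; c < b.size(); ++c) {
          double dx = x[b[a]] - x[b[c]], dy = y[b[a]] - y[b[c]];
          if (dx * dx + dy * dy <= r2) unite(b[a], b[c]);
        }
      // forward half of the 8-neighbourhood to visit each pair once
      const int offs[4][2] = {{1, 0}, {-1, 1}, {0, 1}, {1, 1}};
      for (auto& o : offs) {
        int jx = ix + o[0], jy = iy + o[1];
        if (jx < 0 || jx >= g.nx || jy < 0 || jy >= g.ny) continue;
        const std::vector<int>& b2 = g.buckets[(size_t)jy * g.nx + jx];
        for (int a : b)
          for (int c : b2) {
            double dx = x[a] - x[c], dy = y[a] - y[c];
            if (dx * dx + dy * dy <= r2) unite(a, c);
          }
      }
    }
  }
  // relabel roots consecutively in first-appearance order
  std::vector<int> label(n, 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    if (label[r] == 0) label[r] = ++next;
    comp[i] = label[r];
  }
  return comp;
}

// Minimum distance from each point to a set of segments
// (x0,y0)-(x1,y1). Returns +Inf when there are no segments.
// [[Rcpp::export(name = ".dist_to_segments_cpp")]]
NumericVector dist_to_segments_cpp(NumericVector px, NumericVector py,
                                   NumericVector x0, NumericVector y0,
                                   NumericVector x1, NumericVector y1) {
  int n = px.size(), m = x0.size();
  NumericVector out(n, R_PosInf);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int s = 0; s < m; ++s) {
      double vx = x1[s] - x0[s], vy = y1[s] - y0[s];
      double wx = px[i] - x0[s], wy = py[i] - y0[s];
      double L2 = vx * vx + vy * vy;
      double t = L2 > 0 ? (wx * vx + wy * vy) / L2 : 0.0;
      if (t < 0) t = 0; else if (t > 1) t = 1;
      double dx = wx - t * vx, dy = wy - t * vy;
      double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Area of (union of disks A) \ (union of disks B) by scanline integration:
// per scanline the x-coverage of each union is an exact interval union and
// the set difference is exact interval arithmetic; integration over y uses
// the midpoint rule with step dy.
// [[Rcpp::export(name = ".disk_region_area_cpp")]]
double disk_region_area_cpp(NumericVector ax, NumericVector ay, double ra,
                            NumericVector bx, NumericVector by, double rb,
                            double dy) {
  int na = ax.size();
  if (na == 0) return 0.0;
  double ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < na; ++i) {
    ymin = std::min(ymin, ay[i] - ra);
    ymax = std::max(ymax, ay[i] + ra);
  }
  typedef std::pair<double, double> Iv;
  std::vector<Iv> A, B, D;

  auto collect = [](const NumericVector& cx, const NumericVector& cy,
                    double r, double yy, std::vector<Iv>& out) {
    out.clear();
    int n = cx.size();
    for (int i = 0; i < n; ++i) {
      double h = r * r - (yy - cy[i]) * (yy - cy[i]);
      if (h > 0) {
        double s = std::sqrt(h);
        out.push_back({cx[i] - s, cx[i] + s});
      }
    }
    if (out.empty()) return;
    std::sort(out.begin(), out.end());
    size_t k = 0;
    for (size_t i = 1; i < out.size(); ++i) {
      if (out[i].first <= out[k].second)
        out[k].second = std::max(out[k].second, out[i].second);
      else out[++k] = out[i];
    }
    out.resize(k + 1);
  };

  double area = 0.0;
  long nsteps = (long)std::ceil((ymax - ymin) / dy);
  for (long s = 0; s < nsteps; ++s) {
    double yy = ymin + (s + 0.5) * dy;
    collect(ax, ay, ra, yy, A);
    if (A.empty()) continue;
    collect(bx, by, rb, yy, B);
    // D = A \ B
    D.clear();
    size_t j = 0;
    for (const Iv& a : A) {
      double lo = a.first;
      while (j < B.size() && B[j].second <= lo) ++j;
      size_t jj = j;
      while (jj < B.size() && B[jj].first < a.second) {
        if (B[jj].first > lo) D.push_back({lo, B[jj].first});
        lo = std::max(lo, B[jj].second);
        if (lo >= a.second) break;
        ++jj;
      }
      if (lo < a.second) D.push_back({lo, a.second});
    }
    double len = 0.0;
    for (const Iv& d : D) len += d.second - d.first;
    area += len * dy;
  }
  return area;
}
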