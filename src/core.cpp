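#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Pixel-center convention: pixel (i, j) of an nx x ny grid sits at continuous
// coordinate (i-1, j-1) (0-based centers at integers). Polygon vertices are in
// the same continuous coordinate frame.

static inline double seg_dist2(double px, double py, double ax, double ay,
                               double bx, double by) {
  double vx = bx - ax, vy = by - ay;
  double wx = px - ax, wy = py - ay;
  double vv = vx * vx + vy * vy;
  double t = vv > 0 ? (wx * vx + wy * vy) / vv : 0.0;
  if (t < 0) t = 0; else if (t > 1) t = 1;
  double dx = px - (ax + t * vx), dy = py - (ay + t * vy);
  return dx * dx + dy * dy;
}

// [[Rcpp::export]]
LogicalMatrix cpp_poly_mask(NumericMatrix verts, int nx, int ny, double eps) {
  int n = verts.nrow();
  LogicalMatrix out(nx, ny);
  if (n < 3) return out;
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int k = 0; k < n; ++k) {
    xmin = std::min(xmin, verts(k, 0)); xmax = std::max(xmax, verts(k, 0));
    ymin = std::min(ymin, verts(k, 1)); ymax = std::max(ymax, verts(k, 1));
  }
  int i0 = std::max(0, (int)std::floor(xmin - eps));
  int i1 = std::min(nx - 1, (int)std::ceil(xmax + eps));
  int j0 = std::max(0, (int)std::floor(ymin - eps));
  int j1 = std::min(ny - 1, (int)std::ceil(ymax + eps));
  double e2 = eps * eps;
  for (int j = j0; j <= j1; ++j) {
    double py = (double)j;
    for (int i = i0; i <= i1; ++i) {
      double px = (double)i;
      // crossing number, half-open rule
      bool inside = false;
      bool boundary = false;
      for (int k = 0; k < n; ++k) {
        int k2 = (k + 1) % n;
        double ax = verts(k, 0), ay = verts(k, 1);
        double bx = verts(k2, 0), by = verts(k2, 1);
        if (eps > 0 && seg_dist2(px, py, ax, ay, bx, by) <= e2) {
          boundary = true; break;
        }
        if ((ay > py) != (by > py)) {
          double xc = ax + (py - ay) / (by - ay) * (bx - ax);
          if (px < xc) inside = !inside;
        }
      }
      out(i, j) = boundary || inside;
    }
  }
  return out;
}

static inline int orient(double ax, double ay, double bx, double by,
                         double cx, double cy) {
  double v = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
  if (v > 1e-12) return 1;
  if (v < -1e-12) return -1;
  return 0;
}

static bool seg_intersect(double ax, double ay, double bx, double by,
                          double cx, double cy, double dx, double dy) {
  int o1 = orient(ax, ay, bx, by, cx, cy);
  int o2 = orient(ax, ay, bx, by, dx, dy);
  int o3 = orient(cx, cy, dx, dy, ax, ay);
  int o4 = orient(cx, cy, dx, dy, bx, by);
  return (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0);
}

// [[Rcpp::export]]
bool cpp_poly_self_intersects(NumericMatrix verts) {
  int n = verts.nrow();
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    for (int j = i + 2; j < n; ++j) {
      int j2 = (j + 1) % n;
      if (i == j2) continue;  // adjacent (wrap)
      if (seg_intersect(verts(i, 0), verts(i, 1), verts(i2, 0), verts(i2, 1),
                        verts(j, 0), verts(j, 1), verts(j2, 0), verts(j2, 1)))
        return true;
    }
  }
  return false;
}

// Cyclic shortest path over n profiles x K candidate offsets.
// node: n x K matrix of node costs.
// edge: numeric vector, dim (n, K, K): edge[i, a, b] = cost between candidate
//       a on profile i and candidate b on profile i+1 (profile n wraps to 1).
// ord: integer vector, 0-based candidate indices in tie-break priority order.
// Exact: enumerates every start offset on profile 1.
// [[Rcpp::export]]
List cpp_dp_cyclic_first(NumericMatrix node, NumericVector edge,
                         IntegerVector ord) {
  int n = node.nrow(), K = node.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  double bestTotal = INF;
  IntegerVector bestPath(n);
  std::vector<double> dp(K), dpn(K);
  std::vector<int> ptr((size_t)n * K, -1);
  auto E = [&](int i, int a, int b) -> double {
    return edge[i + (size_t)n * (a + (size_t)K * b)];
  };
  for (int si = 0; si < K; ++si) {
    int s = ord[si];
    if (!std::isfinite(node(0, s))) continue;
    for (int b = 0; b < K; ++b) dp[b] = INF;
    dp[s] = node(0, s);
    for (int i = 1; i < n; ++i) {
      for (int b = 0; b < K; ++b) {
        double best = INF; int barg = -1;
        for (int ai = 0; ai < K; ++ai) {
          int a = ord[ai];
          if (!std::isfinite(dp[a])) continue;
          double c = dp[a] + E(i - 1, a, b);
          if (c < best) { best = c; barg = a; }
        }
        dpn[b] = std::isfinite(best) ? best + node(i, b) : INF;
        ptr[(size_t)i * K + b] = barg;
      }
      std::swap(dp, dpn);
    }
    // close cycle
    double tot = INF; int last = -1;
    for (int bi = 0; bi < K; ++bi) {
      int b = ord[bi];
      if (!std::isfinite(dp[b])) continue;
      double c = dp[b] + E(n - 1, b, s);
      if (c < tot) { tot = c; last = b; }
    }
    if (tot < bestTotal) {
      bestTotal = tot;
      int b = last;
      for (int i = n - 1; i >= 1; --i) {
        bestPath[i] = b;
        b = ptr[(size_t)i * K + b];
      }
      bestPath[0] = s;
    }
  }
  return List::create(_["path"] = bestPath + 1, _["cost"] = bestTotal,
                      _["feasible"] = std::isfinite(bestTotal));
}

// Second-order cyclic DP: adds a triple cost applied at each interior vertex.
// triple: dim (K, n, K, K): triple[a, i, b, c] = penalty at vertex i when
// profile i-1 takes a, profile i takes b, profile i+1 takes c (wrapping);
// the candidate-a axis is fastest for cache-friendly inner loops.
// Start offset on profile 1 is enumerated exactly; the wrap triple at vertex 1
// (which needs offset 2 before the DP has fixed it) is omitted, so the result
// is exact for pairwise graphs and near-optimal when triple costs are present.
// [[Rcpp::export]]
List cpp_dp_cyclic_second(NumericMatrix node, NumericVector edge,
                          NumericVector triple, IntegerVector ord) {
  int n = node.nrow(), K = node.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  const double* tp = REAL(triple);
  auto E = [&](int i, int a, int b) -> double {
    return edge[i + (size_t)n * (a + (size_t)K * b)];
  };
  double bestTotal = INF;
  IntegerVector bestPath(n);
  // dp over states (a = offset at stage i-1, b = offset at stage i),
  // stored as dp[b*K + a] so the predecessor scan over a is contiguous
  std::vector<double> dp((size_t)K * K), dpn((size_t)K * K);
  std::vector<int> ptr((size_t)n * K * K, -1);
  std::vector<int> tmpPath(n);
  for (int si = 0; si < K; ++si) {
    int s = ord[si];
    if (!std::isfinite(node(0, s))) continue;
    std::fill(dp.begin(), dp.end(), INF);
    for (int b = 0; b < K; ++b)
      dp[(size_t)b * K + s] = node(0, s) + node(1, b) + E(0, s, b);
    for (int i = 2; i < n; ++i) {
      std::fill(dpn.begin(), dpn.end(), INF);
      for (int b = 0; b < K; ++b) {
        const double* dpb = &dp[(size_t)b * K];
        for (int c = 0; c < K; ++c) {
          double nc = node(i, c);
          if (!std::isfinite(nc)) continue;
          const double* tb = tp + (size_t)K * ((i - 1) +
                                               (size_t)n * (b + (size_t)K * c));
          double best = INF; int barg = -1;
          for (int a = 0; a < K; ++a) {
            double p = dpb[a];
            if (!std::isfinite(p)) continue;
            double cc = p + tb[a];
            if (cc < best) { best = cc; barg = a; }
          }
          if (barg >= 0) {
            dpn[(size_t)c * K + b] = best + nc + E(i - 1, b, c);
            ptr[((size_t)i * K + b) * K + c] = barg;
          }
        }
      }
      std::swap(dp, dpn);
    }
    // close: state (a, b) at the last stage; add edge b->s and the wrap
    // triple at vertex n (a, b, s)
    double tot = INF; int la = -1, lb = -1;
    for (int bi = 0; bi < K; ++bi) {
      int b = ord[bi];
      for (int ai = 0; ai < K; ++ai) {
        int a = ord[ai];
        double p = dp[(size_t)b * K + a];
        if (!std::isfinite(p)) continue;
        double c = p + E(n - 1, b, s) +
          tp[a + (size_t)K * ((n - 1) + (size_t)n * (b + (size_t)K * s))];
        if (c < tot) { tot = c; la = a; lb = b; }
      }
    }
    if (tot < bestTotal) {
      bestTotal = tot;
      int a = la, b = lb;
      tmpPath[n - 1] = b; tmpPath[n - 2] = a;
      for (int i = n - 1; i >= 2; --i) {
        int pa = ptr[((size_t)i * K + a) * K + b];
        b = a; a = pa;
        tmpPath[i - 2] = a;
      }
      for (int i = 0; i < n; ++i) bestPath[i] = tmpPath[i];
      bestPath[0] = s;
    }
  }
  return List::create(_["path"] = bestPath + 1, _["cost"] = bestTotal,
                      _["feasible"] = std::isfinite(bestTotal));
}

// Trilinear sampling of a 3D volume at continuous 0-based voxel coordinates,
// clamped at the edges. vol is column-major with dims d (length 3).
// [[Rcpp::export]]
NumericVector cpp_interp3(NumericVector vol, IntegerVector d,
                          NumericVector x, NumericVector y, NumericVector z) {
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t np = x.size();
  NumericVector out(np);
  for (R_xlen_t p = 0; p < np; ++p) {
    double xx = x[p], yy = y[p], zz = z[p];
    if (xx < 0) xx = 0; if (xx > nx - 1) xx = nx - 1;
    if (yy < 0) yy = 0; if (yy > ny - 1) yy = ny - 1;
    if (zz < 0) zz = 0; if (zz > nz - 1) zz = nz - 1;
    int x0 = (int)std::floor(xx), y0 = (int)std::floor(yy), z0 = (int)std::floor(zz);
    int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
        z1 = std::min(z0 + 1, nz - 1);
    double fx = xx - x0, fy = yy - y0, fz = zz - z0;
    auto V = [&](int i, int j, int k) -> double {
      return vol[i + (size_t)nx * (j + (size_t)ny * k)];
    };
    double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
    double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
    double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
    double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Bilinear sampling of a 2D image at continuous 0-based coordinates, clamped.
// [[Rcpp::export]]
NumericVector cpp_interp2(NumericMatrix img, NumericVector x, NumericVector y) {
  int nx = img.nrow(), ny = img.ncol();
  R_xlen_t np = x.size();
  NumericVector out(np);
  for (R_xlen_t p = 0; p < np; ++p) {
    double xx = x[p], yy = y[p];
    if (xx < 0) xx = 0; if (xx > nx - 1) xx = nx - 1;
    if (yy < 0) yy = 0; if (yy > ny - 1) yy = ny - 1;
    int x0 = (int)std::floor(xx), y0 = (int)std::floor(yy);
    int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1);
    double fx = xx - x0, fy = yy - y0;
    out[p] = img(x0, y0) * (1 - fx) * (1 - fy) + img(x1, y0) * fx * (1 - fy) +
             img(x0, y1) * (1 - fx) * fy + img(x1, y1) * fx * fy;
  }
  return out;
}

#include <queue>

// Quality-guided region-growing phase unwrapping. Starting from the
// highest-quality voxel, voxels are committed in order of a caller-supplied
// quality map; each voxel is unwrapped congruently (value = wrapped + 2*pi*k)
// against the already-committed neighbour that enqueued it.
// [[Rcpp::export]]
NumericVector cpp_unwrap(NumericVector phase, IntegerVector d,
                         LogicalVector mask, NumericVector quality) {
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t N = (R_xlen_t)nx * ny * nz;
  NumericVector out(clone(phase));
  std::vector<char> done(N, 0);
  struct Node { double q; double val; R_xlen_t idx; };
  struct Cmp {
    bool operator()(const Node& a, const Node& b) const { return a.q < b.q; }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  // seed: best quality voxel in mask
  R_xlen_t seed = -1; double bq = -std::numeric_limits<double>::infinity();
  for (R_xlen_t i = 0; i < N; ++i)
    if (mask[i] && quality[i] > bq) { bq = quality[i]; seed = i; }
  if (seed < 0) return out;
  const double TWOPI = 2.0 * M_PI;
  pq.push({bq, phase[seed], seed});
  int dx[6] = {1, -1, 0, 0, 0, 0};
  int dy[6] = {0, 0, 1, -1, 0, 0};
  int dz[6] = {0, 0, 0, 0, 1, -1};
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    if (done[nd.idx]) continue;
    done[nd.idx] = 1;
    out[nd.idx] = nd.val;
    int z = nd.idx / ((R_xlen_t)nx * ny);
    int rem = nd.idx % ((R_xlen_t)nx * ny);
    int y = rem / nx, x = rem % nx;
    for (int k = 0; k < 6; ++k) {
      int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      if (done[j] || !mask[j]) continue;
      double val = phase[j] + TWOPI * std::round((nd.val - phase[j]) / TWOPI);
      pq.push({quality[j], val, j});
    }
  }
  return out;
}
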