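// Geometry kernels: distance transforms, point-to-triangle distance,
// parity voxelization, marching tetrahedra, implicit tube fields,
// grid Dijkstra, volume-compensated smoothing, centreline recentring.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <limits>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static const double BIG = 1e30;

// ---------------------------------------------------------------------------
// 1D squared distance transform (Felzenszwalb & Huttenlocher), spacing h.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 int n, double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      double qq = (double)q * h, vv = (double)v[k] * h;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * qq - 2.0 * vv);
      if (s <= z[k]) { k--; } else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double qq = (double)q * h;
    while (z[k + 1] < qq) k++;
    double vv = (double)v[k] * h;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// Euclidean distance transform of a 3D binary mask: for each foreground voxel,
// distance (mm) to the nearest background voxel centre; background voxels get 0.
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; i++) g[i] = mask[i] ? BIG : 0.0;

  // x pass
  {
    std::vector<double> f(nx), d(nx);
    for (int k = 0; k < nz; k++)
      for (int j = 0; j < ny; j++) {
        R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = 0; i < nx; i++) f[i] = g[base + i];
        dt1d(f, d, nx, spacing[0]);
        for (int i = 0; i < nx; i++) g[base + i] = d[i];
      }
  }
  // y pass
  {
    std::vector<double> f(ny), d(ny);
    for (int k = 0; k < nz; k++)
      for (int i = 0; i < nx; i++) {
        for (int j = 0; j < ny; j++)
          f[j] = g[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
        dt1d(f, d, ny, spacing[1]);
        for (int j = 0; j < ny; j++)
          g[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[j];
      }
  }
  // z pass
  {
    std::vector<double> f(nz), d(nz);
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        for (int k = 0; k < nz; k++)
          f[k] = g[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
        dt1d(f, d, nz, spacing[2]);
        for (int k = 0; k < nz; k++)
          g[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[k];
      }
  }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = std::sqrt(g[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Closest point on triangle (a, b, c) to p; writes it to q, returns the
// squared distance. Region-clamp method.
static double pointTriClosest(const double *p, const double *a,
                              const double *b, const double *c, double *q) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; i++) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  auto finish = [&](double qx, double qy, double qz) {
    q[0] = qx; q[1] = qy; q[2] = qz;
    double dx = p[0] - qx, dy = p[1] - qy, dz = p[2] - qz;
    return dx * dx + dy * dy + dz * dz;
  };
  if (d1 <= 0.0 && d2 <= 0.0) return finish(a[0], a[1], a[2]);

  double bp[3];
  for (int i = 0; i < 3; i++) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) return finish(b[0], b[1], b[2]);

  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return finish(a[0] + v * ab[0], a[1] + v * ab[1], a[2] + v * ab[2]);
  }

  double cp[3];
  for (int i = 0; i < 3; i++) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) return finish(c[0], c[1], c[2]);

  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return finish(a[0] + w * ac[0], a[1] + w * ac[1], a[2] + w * ac[2]);
  }

  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return finish(b[0] + w * (c[0] - b[0]), b[1] + w * (c[1] - b[1]),
                  b[2] + w * (c[2] - b[2]));
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return finish(a[0] + ab[0] * v + ac[0] * w, a[1] + ab[1] * v + ac[1] * w,
                a[2] + ab[2] * v + ac[2] * w);
}

static double pointTriDist2(const double *p, const double *a, const double *b,
                            const double *c) {
  double q[3];
  return pointTriClosest(p, a, b, c, q);
}

// Uniform-grid spatial index over triangles (cells list every triangle whose
// bounding box overlaps the cell); queries expand in Chebyshev shells.
struct TriGrid {
  double o[3];
  double cs;
  int n[3];
  std::vector<std::vector<int> > cells;
  std::vector<double> tv;   // flat 9 doubles per triangle

  R_xlen_t cid(int i, int j, int k) const {
    return (R_xlen_t)i + (R_xlen_t)n[0] * (j + (R_xlen_t)n[1] * k);
  }
  void build(const NumericMatrix &V, const IntegerMatrix &F) {
    int nf = F.nrow();
    double lo[3] = {BIG, BIG, BIG}, hi[3] = {-BIG, -BIG, -BIG};
    for (int i = 0; i < V.nrow(); i++)
      for (int s = 0; s < 3; s++) {
        lo[s] = std::min(lo[s], V(i, s));
        hi[s] = std::max(hi[s], V(i, s));
      }
    double meansz = 0.0;
    for (int t = 0; t < nf; t++) {
      double mn[3] = {BIG, BIG, BIG}, mx[3] = {-BIG, -BIG, -BIG};
      for (int c = 0; c < 3; c++) {
        int vi = F(t, c);
        for (int s = 0; s < 3; s++) {
          mn[s] = std::min(mn[s], V(vi, s));
          mx[s] = std::max(mx[s], V(vi, s));
        }
      }
      meansz += (mx[0] - mn[0]) + (mx[1] - mn[1]) + (mx[2] - mn[2]);
    }
    meansz = nf > 0 ? meansz / (3.0 * nf) : 1.0;
    cs = std::max(meansz * 3.0, 1e-3);
    for (int s = 0; s < 3; s++) {
      o[s] = lo[s] - 0.5 * cs;
      n[s] = std::max(1, (int)std::ceil((hi[s] - o[s]) / cs) + 1);
    }
    // cap the cell count
    while ((double)n[0] * n[1] * n[2] > 4e6) {
      cs *= 1.5;
      for (int s = 0; s < 3; s++)
        n[s] = std::max(1, (int)std::ceil((hi[s] - o[s]) / cs) + 1);
    }
    cells.assign((R_xlen_t)n[0] * n[1] * n[2], std::vector<int>());
    tv.resize((size_t)nf * 9);
    for (int t = 0; t < nf; t++) {
      double mn[3] = {BIG, BIG, BIG}, mx[3] = {-BIG, -BIG, -BIG};
      for (int c = 0; c < 3; c++) {
        int vi = F(t, c);
        for (int s = 0; s < 3; s++) {
          tv[(size_t)t * 9 + c * 3 + s] = V(vi, s);
          mn[s] = std::min(mn[s], V(vi, s));
          mx[s] = std::max(mx[s], V(vi, s));
        }
      }
      int i0 = (int)((mn[0] - o[0]) / cs), i1 = (int)((mx[0] - o[0]) / cs);
      int j0 = (int)((mn[1] - o[1]) / cs), j1 = (int)((mx[1] - o[1]) / cs);
      int k0 = (int)((mn[2] - o[2]) / cs), k1 = (int)((mx[2] - o[2]) / cs);
      for (int k = std::max(0, k0); k <= std::min(n[2] - 1, k1); k++)
        for (int j = std::max(0, j0); j <= std::min(n[1] - 1, j1); j++)
          for (int i = std::max(0, i0); i <= std::min(n[0] - 1, i1); i++)
            cells[cid(i, j, k)].push_back(t);
    }
  }
  double closest(const double *p, double *qbest) const {
    int pc[3];
    for (int s = 0; s < 3; s++) {
      double c = (p[s] - o[s]) / cs;
      int ci = (int)std::floor(c);
      if (ci < 0) ci = 0;
      if (ci > n[s] - 1) ci = n[s] - 1;
      pc[s] = ci;
    }
    double best2 = BIG;
    double q[3];
    int kmax = std::max(std::max(n[0], n[1]), n[2]);
    for (int ring = 0; ring <= kmax; ring++) {
      if (ring >= 2) {
        double lbv = (ring - 1) * cs;
        if (lbv * lbv >= best2) break;
      }
      for (int dk = -ring; dk <= ring; dk++) {
        int k = pc[2] + dk;
        if (k < 0 || k >= n[2]) continue;
        for (int dj = -ring; dj <= ring; dj++) {
          int j = pc[1] + dj;
          if (j < 0 || j >= n[1]) continue;
          bool faceKJ = (std::abs(dk) == ring) || (std::abs(dj) == ring);
          for (int di = -ring; di <= ring; di++) {
            if (!faceKJ && std::abs(di) != ring) continue;
            int i = pc[0] + di;
            if (i < 0 || i >= n[0]) continue;
            const std::vector<int> &cell = cells[cid(i, j, k)];
            for (size_t t = 0; t < cell.size(); t++) {
              const double *tp = &tv[(size_t)cell[t] * 9];
              double d2 = pointTriClosest(p, tp, tp + 3, tp + 6, q);
              if (d2 < best2) {
                best2 = d2;
                qbest[0] = q[0]; qbest[1] = q[1]; qbest[2] = q[2];
              }
            }
          }
        }
      }
    }
    return std::sqrt(best2);
  }

  double dist(const double *p) const {
    int pc[3];
    double outside = 0.0;
    for (int s = 0; s < 3; s++) {
      double c = (p[s] - o[s]) / cs;
      int ci = (int)std::floor(c);
      if (ci < 0) { outside += (0 - c) * (0 - c); ci = 0; }
      if (ci > n[s] - 1) { outside += (c - (n[s] - 1)) * (c - (n[s] - 1)); ci = n[s] - 1; }
      pc[s] = ci;
    }
    double best2 = BIG;
    int kmax = std::max(std::max(n[0], n[1]), n[2]);
    for (int ring = 0; ring <= kmax; ring++) {
      // lower bound of the distance to any cell in this shell
      double lb = (ring - 1) * cs + std::sqrt(outside) * cs * 0.0;
      if (ring >= 2) {
        double lbv = (ring - 1) * cs;
        if (lbv * lbv >= best2) break;
      }
      bool any = false;
      for (int dk = -ring; dk <= ring; dk++) {
        int k = pc[2] + dk;
        if (k < 0 || k >= n[2]) continue;
        for (int dj = -ring; dj <= ring; dj++) {
          int j = pc[1] + dj;
          if (j < 0 || j >= n[1]) continue;
          bool faceKJ = (std::abs(dk) == ring) || (std::abs(dj) == ring);
          for (int di = -ring; di <= ring; di++) {
            if (!faceKJ && std::abs(di) != ring) continue;  // shell only
            int i = pc[0] + di;
            if (i < 0 || i >= n[0]) continue;
            const std::vector<int> &cell = cells[cid(i, j, k)];
            any = true;
            for (size_t q = 0; q < cell.size(); q++) {
              const double *tp = &tv[(size_t)cell[q] * 9];
              double d2 = pointTriDist2(p, tp, tp + 3, tp + 6);
              if (d2 < best2) best2 = d2;
            }
          }
        }
      }
      (void)any;
      (void)lb;
    }
    return std::sqrt(best2);
  }
};

// Unsigned distance from each row of P to the closest point on mesh (V, F).
// [[Rcpp::export]]
NumericVector cpp_point_mesh_distance(NumericMatrix P, NumericMatrix V,
                                      IntegerMatrix F) {
  int np = P.nrow();
  NumericVector out(np);
  TriGrid tg;
  tg.build(V, F);
  for (int i = 0; i < np; i++) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    out[i] = tg.dist(p);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Parity voxelization: voxel centre is inside iff a +x ray crosses the surface
// an odd number of times. Mesh must be closed (caps added by the caller).
// [[Rcpp::export]]
LogicalVector cpp_voxelize_mesh(NumericMatrix V, IntegerMatrix F,
                                IntegerVector dims, NumericVector origin,
                                NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector mask(n);
  int nf = F.nrow();
  // tiny deterministic jitter avoids rays through edges/vertices
  double jy = 0.5 * spacing[1] * 1e-4, jz = 0.5 * spacing[2] * 7e-5;
  std::vector<std::vector<double> > cross((R_xlen_t)ny * nz);
  for (int t = 0; t < nf; t++) {
    int i0 = F(t, 0), i1 = F(t, 1), i2 = F(t, 2);
    double ay = V(i0, 1), az = V(i0, 2), by = V(i1, 1), bz = V(i1, 2),
           cy = V(i2, 1), cz = V(i2, 2);
    double ymin = std::min(ay, std::min(by, cy)),
           ymax = std::max(ay, std::max(by, cy));
    double zmin = std::min(az, std::min(bz, cz)),
           zmax = std::max(az, std::max(bz, cz));
    int j0 = (int)std::ceil((ymin - origin[1] - jy) / spacing[1]);
    int j1 = (int)std::floor((ymax - origin[1] - jy) / spacing[1]);
    int k0 = (int)std::ceil((zmin - origin[2] - jz) / spacing[2]);
    int k1 = (int)std::floor((zmax - origin[2] - jz) / spacing[2]);
    j0 = std::max(j0, 0); j1 = std::min(j1, ny - 1);
    k0 = std::max(k0, 0); k1 = std::min(k1, nz - 1);
    if (j0 > j1 || k0 > k1) continue;
    double ax = V(i0, 0), bx = V(i1, 0), cx = V(i2, 0);
    for (int k = k0; k <= k1; k++) {
      double rz = origin[2] + k * spacing[2] + jz;
      for (int j = j0; j <= j1; j++) {
        double ry = origin[1] + j * spacing[1] + jy;
        // 2D barycentric in (y, z)
        double v0y = by - ay, v0z = bz - az;
        double v1y = cy - ay, v1z = cz - az;
        double v2y = ry - ay, v2z = rz - az;
        double den = v0y * v1z - v1y * v0z;
        if (std::fabs(den) < 1e-14) continue;
        double u = (v2y * v1z - v1y * v2z) / den;
        double v = (v0y * v2z - v2y * v0z) / den;
        if (u < 0 || v < 0 || u + v > 1) continue;
        double x = ax + u * (bx - ax) + v * (cx - ax);
        cross[(R_xlen_t)j + (R_xlen_t)ny * k].push_back(x);
      }
    }
  }
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      std::vector<double> &xs = cross[(R_xlen_t)j + (R_xlen_t)ny * k];
      if (xs.empty()) continue;
      std::sort(xs.begin(), xs.end());
      size_t m = xs.size();
      for (int i = 0; i < nx; i++) {
        double x = origin[0] + i * spacing[0];
        size_t cnt = std::upper_bound(xs.begin(), xs.end(), x) - xs.begin();
        if ((m - cnt) % 2 == 1)
          mask[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
      }
    }
  return mask;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra: iso-surface of a scalar grid (inside where field < iso).
// Watertight via a cube-parity-free 6-tet split sharing the 0-7 diagonal.
// [[Rcpp::export]]
List cpp_marching_tets(NumericVector field, IntegerVector dims,
                       NumericVector origin, NumericVector spacing,
                       double iso) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  auto gid = [&](int i, int j, int k) -> R_xlen_t {
    return (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
  };
  static const int tets[6][4] = {
    {0, 5, 1, 7}, {0, 1, 3, 7}, {0, 3, 2, 7},
    {0, 2, 6, 7}, {0, 6, 4, 7}, {0, 4, 5, 7}};
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  std::unordered_map<uint64_t, int> edgeMap;
  edgeMap.reserve(1 << 18);

  auto edgeVertex = [&](R_xlen_t g0, R_xlen_t g1, const double *p0,
                        const double *p1, double f0, double f1) -> int {
    uint64_t key = (g0 < g1)
      ? (((uint64_t)g0 << 32) | (uint64_t)g1)
      : (((uint64_t)g1 << 32) | (uint64_t)g0);
    auto it = edgeMap.find(key);
    if (it != edgeMap.end()) return it->second;
    double t = (iso - f0) / (f1 - f0);
    t = std::min(1.0, std::max(0.0, t));
    int id = (int)vx.size();
    vx.push_back(p0[0] + t * (p1[0] - p0[0]));
    vy.push_back(p0[1] + t * (p1[1] - p0[1]));
    vz.push_back(p0[2] + t * (p1[2] - p0[2]));
    edgeMap[key] = id;
    return id;
  };

  double cp[8][3];
  double cf[8];
  R_xlen_t cg[8];
  for (int k = 0; k + 1 < nz; k++)
    for (int j = 0; j + 1 < ny; j++)
      for (int i = 0; i + 1 < nx; i++) {
        bool anyIn = false, anyOut = false;
        for (int c = 0; c < 8; c++) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          cg[c] = gid(ci, cj, ck);
          cf[c] = field[cg[c]];
          cp[c][0] = origin[0] + ci * spacing[0];
          cp[c][1] = origin[1] + cj * spacing[1];
          cp[c][2] = origin[2] + ck * spacing[2];
          if (cf[c] < iso) anyIn = true; else anyOut = true;
        }
        if (!anyIn || !anyOut) continue;
        for (int t = 0; t < 6; t++) {
          int a = tets[t][0], b = tets[t][1], c = tets[t][2], d = tets[t][3];
          int idx[4] = {a, b, c, d};
          int inside[4], nin = 0;
          for (int s = 0; s < 3 + 1; s++)
            if (cf[idx[s]] < iso) inside[nin++] = s;
          if (nin == 0 || nin == 4) continue;
          // collect the crossing-edge vertices
          int outv[4], nout = 0;
          bool isin[4] = {false, false, false, false};
          for (int s = 0; s < nin; s++) isin[inside[s]] = true;
          for (int s = 0; s < 4; s++) if (!isin[s]) outv[nout++] = s;
          auto ev = [&](int s0, int s1) {
            int c0 = idx[s0], c1 = idx[s1];
            return edgeVertex(cg[c0], cg[c1], cp[c0], cp[c1], cf[c0], cf[c1]);
          };
          auto emit = [&](int v0, int v1, int v2, const double *inPos) {
            // orient the triangle so its normal points away from the inside
            double ux = vx[v1] - vx[v0], uy = vy[v1] - vy[v0],
                   uz = vz[v1] - vz[v0];
            double wx2 = vx[v2] - vx[v0], wy2 = vy[v2] - vy[v0],
                   wz2 = vz[v2] - vz[v0];
            double nxn = uy * wz2 - uz * wy2;
            double nyn = uz * wx2 - ux * wz2;
            double nzn = ux * wy2 - uy * wx2;
            double dx = vx[v0] - inPos[0], dy = vy[v0] - inPos[1],
                   dz = vz[v0] - inPos[2];
            if (nxn * dx + nyn * dy + nzn * dz < 0) std::swap(v1, v2);
            tri.push_back(v0); tri.push_back(v1); tri.push_back(v2);
          };
          if (nin == 1) {
            int s = inside[0];
            int e0 = ev(s, outv[0]), e1 = ev(s, outv[1]), e2 = ev(s, outv[2]);
            emit(e0, e1, e2, cp[idx[s]]);
          } else if (nin == 3) {
            int s = outv[0];
            int e0 = ev(inside[0], s), e1 = ev(inside[1], s),
                e2 = ev(inside[2], s);
            emit(e0, e1, e2, cp[idx[inside[0]]]);
          } else { // nin == 2: quad split into two triangles
            int iA = inside[0], iB = inside[1], oA = outv[0], oB = outv[1];
            int eAA = ev(iA, oA), eAB = ev(iA, oB),
                eBA = ev(iB, oA), eBB = ev(iB, oB);
            emit(eAA, eAB, eBB, cp[idx[iA]]);
            emit(eAA, eBB, eBA, cp[idx[iA]]);
          }
        }
      }
  int nv = (int)vx.size(), nf = (int)tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; i++) {
    V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i];
  }
  IntegerMatrix Fm(nf, 3);
  for (int i = 0; i < nf; i++) {
    Fm(i, 0) = tri[3 * i]; Fm(i, 1) = tri[3 * i + 1]; Fm(i, 2) = tri[3 * i + 2];
  }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}

// ---------------------------------------------------------------------------
// Implicit tube-union field: f(x) = min over branch polyline segments of
// (distance to segment - interpolated radius). Negative inside the lumen.
struct BranchSegs {
  std::vector<double> ax, ay, az, bx, by, bz, ra, rb;
};

static std::vector<BranchSegs> parseBranches(const List &branches) {
  std::vector<BranchSegs> out;
  for (int b = 0; b < branches.size(); b++) {
    List br = branches[b];
    NumericMatrix P = br["points"];
    NumericVector R = br["radii"];
    BranchSegs bs;
    for (int i = 0; i + 1 < P.nrow(); i++) {
      bs.ax.push_back(P(i, 0)); bs.ay.push_back(P(i, 1)); bs.az.push_back(P(i, 2));
      bs.bx.push_back(P(i + 1, 0)); bs.by.push_back(P(i + 1, 1)); bs.bz.push_back(P(i + 1, 2));
      bs.ra.push_back(R[i]); bs.rb.push_back(R[i + 1]);
    }
    out.push_back(bs);
  }
  return out;
}

static double segField(const BranchSegs &bs, size_t s, double px, double py,
                       double pz) {
  double dx = bs.bx[s] - bs.ax[s], dy = bs.by[s] - bs.ay[s],
         dz = bs.bz[s] - bs.az[s];
  double len2 = dx * dx + dy * dy + dz * dz;
  double t = 0.0;
  if (len2 > 0) {
    t = ((px - bs.ax[s]) * dx + (py - bs.ay[s]) * dy + (pz - bs.az[s]) * dz) / len2;
    t = std::min(1.0, std::max(0.0, t));
  }
  double qx = bs.ax[s] + t * dx, qy = bs.ay[s] + t * dy, qz = bs.az[s] + t * dz;
  double r = bs.ra[s] + t * (bs.rb[s] - bs.ra[s]);
  double ex = px - qx, ey = py - qy, ez = pz - qz;
  return std::sqrt(ex * ex + ey * ey + ez * ez) - r;
}

static double treeField(const std::vector<BranchSegs> &B, double px, double py,
                        double pz) {
  double f = BIG;
  for (size_t b = 0; b < B.size(); b++)
    for (size_t s = 0; s < B[b].ax.size(); s++)
      f = std::min(f, segField(B[b], s, px, py, pz));
  return f;
}

// Field evaluated at arbitrary points.
// [[Rcpp::export]]
NumericVector cpp_tree_field_points(NumericMatrix P, List branches) {
  std::vector<BranchSegs> B = parseBranches(branches);
  NumericVector out(P.nrow());
  for (int i = 0; i < P.nrow(); i++)
    out[i] = treeField(B, P(i, 0), P(i, 1), P(i, 2));
  return out;
}

// Field sampled on a regular grid, touching only voxels near each segment.
// [[Rcpp::export]]
NumericVector cpp_tree_field_grid(IntegerVector dims, NumericVector origin,
                                  NumericVector spacing, List branches,
                                  double margin) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector field(n);
  std::fill(field.begin(), field.end(), margin); // positive far-field
  std::vector<BranchSegs> B = parseBranches(branches);
  for (size_t b = 0; b < B.size(); b++) {
    const BranchSegs &bs = B[b];
    for (size_t s = 0; s < bs.ax.size(); s++) {
      double rmax = std::max(bs.ra[s], bs.rb[s]) + margin;
      double x0 = std::min(bs.ax[s], bs.bx[s]) - rmax,
             x1 = std::max(bs.ax[s], bs.bx[s]) + rmax;
      double y0 = std::min(bs.ay[s], bs.by[s]) - rmax,
             y1 = std::max(bs.ay[s], bs.by[s]) + rmax;
      double z0 = std::min(bs.az[s], bs.bz[s]) - rmax,
             z1 = std::max(bs.az[s], bs.bz[s]) + rmax;
      int i0 = std::max(0, (int)std::ceil((x0 - origin[0]) / spacing[0]));
      int i1 = std::min(nx - 1, (int)std::floor((x1 - origin[0]) / spacing[0]));
      int j0 = std::max(0, (int)std::ceil((y0 - origin[1]) / spacing[1]));
      int j1 = std::min(ny - 1, (int)std::floor((y1 - origin[1]) / spacing[1]));
      int k0 = std::max(0, (int)std::ceil((z0 - origin[2]) / spacing[2]));
      int k1 = std::min(nz - 1, (int)std::floor((z1 - origin[2]) / spacing[2]));
      for (int k = k0; k <= k1; k++) {
        double pz = origin[2] + k * spacing[2];
        for (int j = j0; j <= j1; j++) {
          double py = origin[1] + j * spacing[1];
          R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
          for (int i = i0; i <= i1; i++) {
            double px = origin[0] + i * spacing[0];
            double f = segField(bs, s, px, py, pz);
            if (f < field[base + i]) field[base + i] = f;
          }
        }
      }
    }
  }
  return field;
}

// Segment grid: cells list tube segments whose radius-dilated bounding box
// overlaps the cell, so field evaluations near the surface see every
// relevant segment while skipping the rest of the tree.
struct SegGrid {
  double o[3], cs;
  int n[3];
  std::vector<std::vector<std::pair<int, int> > > cells; // (branch, segment)
  double farval;

  R_xlen_t cid(int i, int j, int k) const {
    return (R_xlen_t)i + (R_xlen_t)n[0] * (j + (R_xlen_t)n[1] * k);
  }
  void build(const std::vector<BranchSegs> &B, double margin) {
    farval = margin;
    double lo[3] = {BIG, BIG, BIG}, hi[3] = {-BIG, -BIG, -BIG};
    double rmax = 0;
    for (size_t b = 0; b < B.size(); b++)
      for (size_t s = 0; s < B[b].ax.size(); s++) {
        double pr = std::max(B[b].ra[s], B[b].rb[s]);
        rmax = std::max(rmax, pr);
        lo[0] = std::min(lo[0], std::min(B[b].ax[s], B[b].bx[s]) - pr - margin);
        hi[0] = std::max(hi[0], std::max(B[b].ax[s], B[b].bx[s]) + pr + margin);
        lo[1] = std::min(lo[1], std::min(B[b].ay[s], B[b].by[s]) - pr - margin);
        hi[1] = std::max(hi[1], std::max(B[b].ay[s], B[b].by[s]) + pr + margin);
        lo[2] = std::min(lo[2], std::min(B[b].az[s], B[b].bz[s]) - pr - margin);
        hi[2] = std::max(hi[2], std::max(B[b].az[s], B[b].bz[s]) + pr + margin);
      }
    cs = std::max(2.0, rmax / 2.0);
    for (int s = 0; s < 3; s++) {
      o[s] = lo[s];
      n[s] = std::max(1, (int)std::ceil((hi[s] - o[s]) / cs) + 1);
    }
    while ((double)n[0] * n[1] * n[2] > 2e6) {
      cs *= 1.5;
      for (int s = 0; s < 3; s++)
        n[s] = std::max(1, (int)std::ceil((hi[s] - o[s]) / cs) + 1);
    }
    cells.assign((R_xlen_t)n[0] * n[1] * n[2],
                 std::vector<std::pair<int, int> >());
    for (size_t b = 0; b < B.size(); b++)
      for (size_t s = 0; s < B[b].ax.size(); s++) {
        double pr = std::max(B[b].ra[s], B[b].rb[s]) + farval + cs * 0.5;
        double mn[3] = {std::min(B[b].ax[s], B[b].bx[s]) - pr,
                        std::min(B[b].ay[s], B[b].by[s]) - pr,
                        std::min(B[b].az[s], B[b].bz[s]) - pr};
        double mx[3] = {std::max(B[b].ax[s], B[b].bx[s]) + pr,
                        std::max(B[b].ay[s], B[b].by[s]) + pr,
                        std::max(B[b].az[s], B[b].bz[s]) + pr};
        int i0 = std::max(0, (int)((mn[0] - o[0]) / cs));
        int i1 = std::min(n[0] - 1, (int)((mx[0] - o[0]) / cs));
        int j0 = std::max(0, (int)((mn[1] - o[1]) / cs));
        int j1 = std::min(n[1] - 1, (int)((mx[1] - o[1]) / cs));
        int k0 = std::max(0, (int)((mn[2] - o[2]) / cs));
        int k1 = std::min(n[2] - 1, (int)((mx[2] - o[2]) / cs));
        for (int k = k0; k <= k1; k++)
          for (int j = j0; j <= j1; j++)
            for (int i = i0; i <= i1; i++)
              cells[cid(i, j, k)].push_back(std::make_pair((int)b, (int)s));
      }
  }
  double eval(const std::vector<BranchSegs> &B, double x, double y,
              double z) const {
    int pc[3];
    double pp[3] = {x, y, z};
    for (int s = 0; s < 3; s++) {
      int ci = (int)((pp[s] - o[s]) / cs);
      if (ci < 0 || ci >= n[s]) return farval;
      pc[s] = ci;
    }
    const std::vector<std::pair<int, int> > &cell = cells[cid(pc[0], pc[1], pc[2])];
    double f = farval;
    for (size_t q = 0; q < cell.size(); q++)
      f = std::min(f, segField(B[cell[q].first], cell[q].second, x, y, z));
    return f;
  }
};

// Newton projection of points onto the zero level set of the tube-union field.
// [[Rcpp::export]]
NumericMatrix cpp_project_to_tree(NumericMatrix P, List branches, int iters) {
  std::vector<BranchSegs> B = parseBranches(branches);
  SegGrid sg;
  sg.build(B, 4.0);
  NumericMatrix out = clone(P);
  const double h = 1e-4;
  for (int i = 0; i < out.nrow(); i++) {
    double x = out(i, 0), y = out(i, 1), z = out(i, 2);
    for (int it = 0; it < iters; it++) {
      double f = sg.eval(B, x, y, z);
      if (std::fabs(f) < 1e-7) break;
      double gx = (sg.eval(B, x + h, y, z) - sg.eval(B, x - h, y, z)) / (2 * h);
      double gy = (sg.eval(B, x, y + h, z) - sg.eval(B, x, y - h, z)) / (2 * h);
      double gz = (sg.eval(B, x, y, z + h) - sg.eval(B, x, y, z - h)) / (2 * h);
      double g2 = gx * gx + gy * gy + gz * gz;
      if (g2 < 1e-12) break;
      double step = f / g2;
      // conservative cap keeps creased-junction vertices stable
      double nrm = std::sqrt(g2);
      double maxstep = 1.0;
      if (std::fabs(step) * nrm > maxstep) step = maxstep / nrm * (step > 0 ? 1 : -1);
      x -= step * gx; y -= step * gy; z -= step * gz;
    }
    out(i, 0) = x; out(i, 1) = y; out(i, 2) = z;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Dijkstra over foreground voxels (dt > 0), 26-connectivity, medialness cost
// len * ((1/dt_u^2) + (1/dt_v^2)) / 2. Returns distances and parents (-1 none).
// [[Rcpp::export]]
List cpp_dijkstra_grid(IntegerVector dims, NumericVector spacing,
                       NumericVector dt, int source) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> dist(n, BIG);
  std::vector<int> parent(n, -1);
  typedef std::pair<double, R_xlen_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  if (source < 0 || source >= n || dt[source] <= 0)
    stop("Dijkstra source voxel is not inside the lumen");
  dist[source] = 0.0;
  pq.push(QE(0.0, source));
  int dxs[26], dys[26], dzs[26];
  double lens[26];
  int m = 0;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        dxs[m] = dx; dys[m] = dy; dzs[m] = dz;
        double lx = dx * spacing[0], ly = dy * spacing[1], lz = dz * spacing[2];
        lens[m] = std::sqrt(lx * lx + ly * ly + lz * lz);
        m++;
      }
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    R_xlen_t u = top.second;
    if (top.first > dist[u]) continue;
    int ui = (int)(u % nx), uj = (int)((u / nx) % ny), uk = (int)(u / ((R_xlen_t)nx * ny));
    double wu = 1.0 / (dt[u] * dt[u]);
    for (int e = 0; e < 26; e++) {
      int vi = ui + dxs[e], vj = uj + dys[e], vk = uk + dzs[e];
      if (vi < 0 || vi >= nx || vj < 0 || vj >= ny || vk < 0 || vk >= nz) continue;
      R_xlen_t v = (R_xlen_t)vi + (R_xlen_t)nx * (vj + (R_xlen_t)ny * vk);
      if (dt[v] <= 0) continue;
      double w = lens[e] * 0.5 * (wu + 1.0 / (dt[v] * dt[v]));
      if (dist[u] + w < dist[v]) {
        dist[v] = dist[u] + w;
        parent[v] = (int)u;
        pq.push(QE(dist[v], v));
      }
    }
  }
  NumericVector dOut(n);
  IntegerVector pOut(n);
  for (R_xlen_t i = 0; i < n; i++) {
    dOut[i] = dist[i];
    pOut[i] = parent[i];
  }
  return List::create(_["dist"] = dOut, _["parent"] = pOut);
}

// 26-connected component labels (0 = background), labels 1..k.
// [[Rcpp::export]]
IntegerVector cpp_connected_components26(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s] != 0) continue;
    next++;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t u = stack.back(); stack.pop_back();
      int ui = (int)(u % nx), uj = (int)((u / nx) % ny),
          uk = (int)(u / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            if (!dx && !dy && !dz) continue;
            int vi = ui + dx, vj = uj + dy, vk = uk + dz;
            if (vi < 0 || vi >= nx || vj < 0 || vj >= ny || vk < 0 || vk >= nz)
              continue;
            R_xlen_t v = (R_xlen_t)vi + (R_xlen_t)nx * (vj + (R_xlen_t)ny * vk);
            if (mask[v] && lab[v] == 0) {
              lab[v] = next;
              stack.push_back(v);
            }
          }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Taubin lambda/mu smoothing with per-iteration volume compensation along
// vertex normals. Boundary vertices (edges with a single incident face) are
// frozen, so open caps keep their shape. Requires outward-oriented faces.
static double signedVolume(const std::vector<double> &x,
                           const std::vector<double> &y,
                           const std::vector<double> &z,
                           const IntegerMatrix &F) {
  double vol = 0.0;
  for (int t = 0; t < F.nrow(); t++) {
    int a = F(t, 0), b = F(t, 1), c = F(t, 2);
    vol += (x[a] * (y[b] * z[c] - z[b] * y[c]) -
            y[a] * (x[b] * z[c] - z[b] * x[c]) +
            z[a] * (x[b] * y[c] - y[b] * x[c])) / 6.0;
  }
  return vol;
}

// [[Rcpp::export]]
NumericMatrix cpp_smooth_volpres(NumericMatrix V, IntegerMatrix F,
                                 IntegerMatrix Fcap, int iterations,
                                 double lambda) {
  // F: the open mesh faces (smoothed); Fcap: closing caps used only for volume
  int nv = V.nrow();
  std::vector<double> x(nv), y(nv), z(nv);
  for (int i = 0; i < nv; i++) { x[i] = V(i, 0); y[i] = V(i, 1); z[i] = V(i, 2); }

  // adjacency + boundary flags from the open mesh
  std::unordered_map<uint64_t, int> edgeCount;
  std::vector<std::vector<int> > nbr(nv);
  auto ekey = [](int a, int b) {
    return (a < b) ? (((uint64_t)a << 32) | (uint64_t)b)
                   : (((uint64_t)b << 32) | (uint64_t)a);
  };
  for (int t = 0; t < F.nrow(); t++) {
    int idx[3] = {F(t, 0), F(t, 1), F(t, 2)};
    for (int s = 0; s < 3; s++) {
      int a = idx[s], b = idx[(s + 1) % 3];
      uint64_t k = ekey(a, b);
      if (edgeCount.find(k) == edgeCount.end()) {
        edgeCount[k] = 1;
        nbr[a].push_back(b);
        nbr[b].push_back(a);
      } else {
        edgeCount[k]++;
      }
    }
  }
  std::vector<bool> frozen(nv, false);
  for (auto &kv : edgeCount)
    if (kv.second == 1) {
      frozen[(int)(kv.first >> 32)] = true;
      frozen[(int)(kv.first & 0xffffffffULL)] = true;
    }

  // combined face list for volume (open faces + caps)
  int nfAll = F.nrow() + Fcap.nrow();
  IntegerMatrix Fall(nfAll, 3);
  for (int t = 0; t < F.nrow(); t++)
    for (int s = 0; s < 3; s++) Fall(t, s) = F(t, s);
  for (int t = 0; t < Fcap.nrow(); t++)
    for (int s = 0; s < 3; s++) Fall(F.nrow() + t, s) = Fcap(t, s);

  double V0 = signedVolume(x, y, z, Fall);
  double sgn = (V0 >= 0) ? 1.0 : -1.0;

  std::vector<double> nxv(nv), nyv(nv), nzv(nv), area(nv);
  std::vector<double> lx(nv), ly(nv), lz(nv);
  double mu = -lambda * 1.06; // Taubin shrink/inflate pair

  for (int it = 0; it < iterations; it++) {
    for (int pass = 0; pass < 2; pass++) {
      double w = (pass == 0) ? lambda : mu;
      // vertex normals for this pass: the Laplacian displacement acts along
      // the normal only, so staircase (normal oscillation) is damped while
      // vertices do not slide tangentially on already-smooth surfaces
      std::fill(nxv.begin(), nxv.end(), 0.0);
      std::fill(nyv.begin(), nyv.end(), 0.0);
      std::fill(nzv.begin(), nzv.end(), 0.0);
      for (int t = 0; t < F.nrow(); t++) {
        int a = F(t, 0), b = F(t, 1), c = F(t, 2);
        double ux = x[b] - x[a], uy = y[b] - y[a], uz = z[b] - z[a];
        double wx = x[c] - x[a], wy = y[c] - y[a], wz = z[c] - z[a];
        double cxn = uy * wz - uz * wy, cyn = uz * wx - ux * wz,
               czn = ux * wy - uy * wx;
        nxv[a] += cxn; nxv[b] += cxn; nxv[c] += cxn;
        nyv[a] += cyn; nyv[b] += cyn; nyv[c] += cyn;
        nzv[a] += czn; nzv[b] += czn; nzv[c] += czn;
      }
      for (int i = 0; i < nv; i++) {
        if (frozen[i] || nbr[i].empty()) { lx[i] = x[i]; ly[i] = y[i]; lz[i] = z[i]; continue; }
        double sx = 0, sy = 0, sz = 0;
        for (int jn : nbr[i]) { sx += x[jn]; sy += y[jn]; sz += z[jn]; }
        double inv = 1.0 / nbr[i].size();
        double dx = sx * inv - x[i], dy = sy * inv - y[i], dz = sz * inv - z[i];
        double nn = std::sqrt(nxv[i] * nxv[i] + nyv[i] * nyv[i] + nzv[i] * nzv[i]);
        if (nn > 1e-20) {
          double dot = (dx * nxv[i] + dy * nyv[i] + dz * nzv[i]) / (nn * nn);
          dx = dot * nxv[i]; dy = dot * nyv[i]; dz = dot * nzv[i];
        }
        lx[i] = x[i] + w * dx;
        ly[i] = y[i] + w * dy;
        lz[i] = z[i] + w * dz;
      }
      x.swap(lx); y.swap(ly); z.swap(lz);
    }
    // volume compensation along area-weighted vertex normals
    for (int corr = 0; corr < 2; corr++) {
      double Vc = signedVolume(x, y, z, Fall);
      double dV = V0 - Vc;
      if (std::fabs(dV) < 1e-12 * std::fabs(V0) + 1e-15) break;
      std::fill(nxv.begin(), nxv.end(), 0.0);
      std::fill(nyv.begin(), nyv.end(), 0.0);
      std::fill(nzv.begin(), nzv.end(), 0.0);
      std::fill(area.begin(), area.end(), 0.0);
      for (int t = 0; t < F.nrow(); t++) {
        int a = F(t, 0), b = F(t, 1), c = F(t, 2);
        double ux = x[b] - x[a], uy = y[b] - y[a], uz = z[b] - z[a];
        double wx = x[c] - x[a], wy = y[c] - y[a], wz = z[c] - z[a];
        double cxn = uy * wz - uz * wy, cyn = uz * wx - ux * wz,
               czn = ux * wy - uy * wx;
        double aA = 0.5 * std::sqrt(cxn * cxn + cyn * cyn + czn * czn);
        for (int s = 0; s < 3; s++) {
          int vi = F(t, s);
          nxv[vi] += cxn; nyv[vi] += cyn; nzv[vi] += czn;
          area[vi] += aA / 3.0;
        }
      }
      double denom = 0.0;
      for (int i = 0; i < nv; i++) if (!frozen[i]) denom += area[i];
      if (denom <= 0) break;
      double delta = sgn * dV / denom;
      for (int i = 0; i < nv; i++) {
        if (frozen[i]) continue;
        double nn = std::sqrt(nxv[i] * nxv[i] + nyv[i] * nyv[i] + nzv[i] * nzv[i]);
        if (nn < 1e-20) continue;
        x[i] += delta * nxv[i] / nn;
        y[i] += delta * nyv[i] / nn;
        z[i] += delta * nzv[i] / nn;
      }
    }
  }
  NumericMatrix out(nv, 3);
  for (int i = 0; i < nv; i++) { out(i, 0) = x[i]; out(i, 1) = y[i]; out(i, 2) = z[i]; }
  return out;
}

// ---------------------------------------------------------------------------
// Recentre centreline samples onto the local medial axis: repeatedly find the
// nearest wall point, then line-search away from it (within the plane
// perpendicular to the local direction) for the position maximising the
// distance to the wall.
// [[Rcpp::export]]
List cpp_recenter_points(NumericMatrix P, NumericMatrix Dir, NumericMatrix V,
                         IntegerMatrix F, double step0, int rounds,
                         double max_disp) {
  (void)step0;
  TriGrid tg;
  tg.build(V, F);
  int np = P.nrow();
  NumericMatrix out = clone(P);
  NumericVector rad(np);
  for (int i = 0; i < np; i++) {
    double d[3] = {Dir(i, 0), Dir(i, 1), Dir(i, 2)};
    double dn = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (dn < 1e-12) { d[0] = 1; d[1] = 0; d[2] = 0; dn = 1; }
    for (int s = 0; s < 3; s++) d[s] /= dn;
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    double p0[3] = {p[0], p[1], p[2]};
    double q[3];
    double best = tg.closest(p, q);
    for (int it = 0; it < rounds; it++) {
      // inward direction: away from the nearest wall point, projected onto
      // the plane perpendicular to the local path direction
      double u[3] = {p[0] - q[0], p[1] - q[1], p[2] - q[2]};
      double ud = u[0] * d[0] + u[1] * d[1] + u[2] * d[2];
      for (int s = 0; s < 3; s++) u[s] -= ud * d[s];
      double un = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
      if (un < 1e-9) break;
      for (int s = 0; s < 3; s++) u[s] /= un;
      // golden-section maximisation of wall distance along p + t*u
      double lo = 0.0, hi = std::min(2.0 * best, max_disp);
      const double gr = 0.618033988749895;
      double t1 = hi - gr * (hi - lo), t2 = lo + gr * (hi - lo);
      double c1[3], c2[3], qq[3];
      double f1 = 0, f2 = 0;
      for (int s = 0; s < 3; s++) c1[s] = p[s] + t1 * u[s];
      for (int s = 0; s < 3; s++) c2[s] = p[s] + t2 * u[s];
      f1 = tg.closest(c1, qq);
      f2 = tg.closest(c2, qq);
      for (int gs = 0; gs < 9; gs++) {
        if (f1 < f2) {
          lo = t1; t1 = t2; f1 = f2;
          t2 = lo + gr * (hi - lo);
          for (int s = 0; s < 3; s++) c2[s] = p[s] + t2 * u[s];
          f2 = tg.closest(c2, qq);
        } else {
          hi = t2; t2 = t1; f2 = f1;
          t1 = hi - gr * (hi - lo);
          for (int s = 0; s < 3; s++) c1[s] = p[s] + t1 * u[s];
          f1 = tg.closest(c1, qq);
        }
      }
      double tbest = 0.5 * (t1 + t2);
      double cand[3] = {p[0] + tbest * u[0], p[1] + tbest * u[1],
                        p[2] + tbest * u[2]};
      double dd0 = cand[0] - p0[0], dd1 = cand[1] - p0[1], dd2 = cand[2] - p0[2];
      if (std::sqrt(dd0 * dd0 + dd1 * dd1 + dd2 * dd2) > max_disp) break;
      double fc = tg.closest(cand, qq);
      if (fc <= best + 1e-10) break;
      best = fc;
      for (int s = 0; s < 3; s++) { p[s] = cand[s]; q[s] = qq[s]; }
    }
    out(i, 0) = p[0]; out(i, 1) = p[1]; out(i, 2) = p[2];
    rad[i] = best;
  }
  return List::create(_["points"] = out, _["radius"] = rad);
}
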