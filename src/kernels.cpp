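// Geometry kernels: vertical-ray rasterization of triangle meshes,
// voxel-counting Boolean difference oracle, and closest-point queries
// on a triangle mesh via a uniform spatial grid.
//
// Conventions: vertices are N x 3 (mm), faces are M x 3 with 0-based
// indices, rays are cast along -z at cell centers x_i = ox + (i + 0.5) * step.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

namespace {

inline double tri_z_at(double px, double py,
                       double ax, double ay, double az,
                       double bx, double by, double bz,
                       double cx, double cy, double cz,
                       bool &inside) {
  // 2D barycentric test in the xy plane; tolerant on edges so that rays
  // on shared edges are claimed by at least one triangle.
  const double v0x = bx - ax, v0y = by - ay;
  const double v1x = cx - ax, v1y = cy - ay;
  const double v2x = px - ax, v2y = py - ay;
  const double den = v0x * v1y - v1x * v0y;
  inside = false;
  if (std::fabs(den) < 1e-14) return 0.0;  // degenerate in xy (wall)
  const double u = (v2x * v1y - v1x * v2y) / den;
  const double v = (v0x * v2y - v2x * v0y) / den;
  const double eps = 1e-9;
  if (u < -eps || v < -eps || u + v > 1.0 + eps) return 0.0;
  inside = true;
  return az + u * (bz - az) + v * (cz - az);
}

struct HitAccum {
  std::vector<double> zmin, zmax;
  std::vector<int> nhit;
  int nx, ny;
  void init(int nx_, int ny_) {
    nx = nx_; ny = ny_;
    zmin.assign((size_t)nx * ny, std::numeric_limits<double>::infinity());
    zmax.assign((size_t)nx * ny, -std::numeric_limits<double>::infinity());
    nhit.assign((size_t)nx * ny, 0);
  }
};

void rasterize(const NumericMatrix &V, const IntegerMatrix &F,
               double ox, double oy, double step, int nx, int ny,
               HitAccum &acc) {
  acc.init(nx, ny);
  const int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    const int ia = F(f, 0), ib = F(f, 1), ic = F(f, 2);
    const double ax = V(ia, 0), ay = V(ia, 1), az = V(ia, 2);
    const double bx = V(ib, 0), by = V(ib, 1), bz = V(ib, 2);
    const double cx = V(ic, 0), cy = V(ic, 1), cz = V(ic, 2);
    const double xmin = std::min(ax, std::min(bx, cx));
    const double xmax = std::max(ax, std::max(bx, cx));
    const double ymin = std::min(ay, std::min(by, cy));
    const double ymax = std::max(ay, std::max(by, cy));
    int i0 = (int)std::ceil((xmin - ox) / step - 0.5 - 1e-12);
    int i1 = (int)std::floor((xmax - ox) / step - 0.5 + 1e-12);
    int j0 = (int)std::ceil((ymin - oy) / step - 0.5 - 1e-12);
    int j1 = (int)std::floor((ymax - oy) / step - 0.5 + 1e-12);
    i0 = std::max(i0, 0); i1 = std::min(i1, nx - 1);
    j0 = std::max(j0, 0); j1 = std::min(j1, ny - 1);
    for (int i = i0; i <= i1; ++i) {
      const double px = ox + (i + 0.5) * step;
      for (int j = j0; j <= j1; ++j) {
        const double py = oy + (j + 0.5) * step;
        bool inside;
        const double z = tri_z_at(px, py, ax, ay, az, bx, by, bz,
                                  cx, cy, cz, inside);
        if (inside) {
          const size_t k = (size_t)i + (size_t)nx * j;
          if (z < acc.zmin[k]) acc.zmin[k] = z;
          if (z > acc.zmax[k]) acc.zmax[k] = z;
          acc.nhit[k]++;
        }
      }
    }
  }
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_raster_heights(NumericMatrix V, IntegerMatrix F,
                                 double ox, double oy, double step,
                                 int nx, int ny) {
  HitAccum acc;
  rasterize(V, F, ox, oy, step, nx, ny, acc);
  NumericMatrix H(nx, ny);
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j) {
      const size_t k = (size_t)i + (size_t)nx * j;
      H(i, j) = acc.nhit[k] > 0 ? acc.zmax[k] : NA_REAL;
    }
  return H;
}

// Voxel-counting Boolean difference: counts voxel centers inside shell a
// and not inside shell b (dilated upward by `clearance` in offset mode).
// Shells are z-monotone solids by construction (single [zmin, zmax]
// occupancy interval per column). mode: 0 = offset, 1 = threshold.
// [[Rcpp::export]]
double cpp_voxel_diff_volume(NumericMatrix Va, IntegerMatrix Fa,
                             NumericMatrix Vb, IntegerMatrix Fb,
                             double ox, double oy, double step,
                             int nx, int ny,
                             double zmin, double zstep, int nz,
                             double clearance, int mode) {
  HitAccum a, b;
  rasterize(Va, Fa, ox, oy, step, nx, ny, a);
  rasterize(Vb, Fb, ox, oy, step, nx, ny, b);
  const double voxvol = step * step * zstep;
  double total = 0.0;
  for (size_t k = 0; k < (size_t)nx * ny; ++k) {
    if (a.nhit[k] == 0) continue;
    const double alo = a.zmin[k], ahi = a.zmax[k];
    double blo, bhi;
    if (b.nhit[k] > 0) {
      blo = b.zmin[k];
      bhi = b.zmax[k] + (mode == 0 ? clearance : 0.0);
    } else {
      blo = 1.0; bhi = 0.0;  // empty
    }
    long cnt = 0;
    for (int m = 0; m < nz; ++m) {
      const double z = zmin + (m + 0.5) * zstep;
      if (z >= alo && z <= ahi && !(z >= blo && z <= bhi)) ++cnt;
    }
    if (mode == 1) {
      // threshold gate on the exact column thickness (voxel-quantized
      // thickness would misclassify columns within half a voxel of the
      // clearance)
      const double t = (b.nhit[k] > 0) ? (ahi - bhi) : (ahi - alo);
      if (t <= clearance) cnt = 0;
    }
    total += cnt * voxvol;
  }
  return total;
}

// ---- closest point on triangle (Ericson, Real-Time Collision Detection) ----

namespace {

struct Vec3 { double x, y, z; };
inline Vec3 vsub(const Vec3 &a, const Vec3 &b) { return {a.x-b.x, a.y-b.y, a.z-b.z}; }
inline Vec3 vadd(const Vec3 &a, const Vec3 &b) { return {a.x+b.x, a.y+b.y, a.z+b.z}; }
inline Vec3 vscale(const Vec3 &a, double s) { return {a.x*s, a.y*s, a.z*s}; }
inline double vdot(const Vec3 &a, const Vec3 &b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
inline Vec3 vcross(const Vec3 &a, const Vec3 &b) {
  return {a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x};
}

Vec3 closest_on_triangle(const Vec3 &p, const Vec3 &a, const Vec3 &b,
                         const Vec3 &c) {
  Vec3 ab = vsub(b, a), ac = vsub(c, a), ap = vsub(p, a);
  double d1 = vdot(ab, ap), d2 = vdot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  Vec3 bp = vsub(p, b);
  double d3 = vdot(ab, bp), d4 = vdot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return vadd(a, vscale(ab, v));
  }
  Vec3 cp = vsub(p, c);
  double d5 = vdot(ab, cp), d6 = vdot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return vadd(a, vscale(ac, w));
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return vadd(b, vscale(vsub(c, b), w));
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return vadd(a, vadd(vscale(ab, v), vscale(ac, w)));
}

}  // namespace

// Closest point on the surface of (V, F) for each query row of Q, searched
// within maxRadius. Returns closest points, outward face normals of the
// hit faces, signed-capable distances (unsigned here), face index (1-based,
// NA when unmatched).
// [[Rcpp::export]]
List cpp_closest_points(NumericMatrix Q, NumericMatrix V, IntegerMatrix F,
                        double maxRadius) {
  const int nq = Q.nrow(), nf = F.nrow();

  // uniform grid over mesh bbox, cell size tied to triangle size
  double bb[6] = {R_PosInf, R_PosInf, R_PosInf, R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < V.nrow(); ++i)
    for (int d = 0; d < 3; ++d) {
      bb[d] = std::min(bb[d], V(i, d));
      bb[3 + d] = std::max(bb[3 + d], V(i, d));
    }
  double mean_edge = 0.0;
  for (int f = 0; f < std::min(nf, 2000); ++f) {
    Vec3 a{V(F(f,0),0), V(F(f,0),1), V(F(f,0),2)};
    Vec3 b{V(F(f,1),0), V(F(f,1),1), V(F(f,1),2)};
    Vec3 e = vsub(b, a);
    mean_edge += std::sqrt(vdot(e, e));
  }
  mean_edge /= std::min(nf, 2000);
  const double h = std::max(2.0 * mean_edge, 1e-3);
  int gx = std::max(1, (int)std::ceil((bb[3] - bb[0]) / h));
  int gy = std::max(1, (int)std::ceil((bb[4] - bb[1]) / h));
  int gz = std::max(1, (int)std::ceil((bb[5] - bb[2]) / h));
  gx = std::min(gx, 512); gy = std::min(gy, 512); gz = std::min(gz, 512);
  const double hx = (bb[3] - bb[0]) / gx + 1e-12;
  const double hy = (bb[4] - bb[1]) / gy + 1e-12;
  const double hz = (bb[5] - bb[2]) / gz + 1e-12;
  std::vector< std::vector<int> > cells((size_t)gx * gy * gz);
  auto cell_of = [&](double x, double y, double z, int &ci, int &cj, int &ck) {
    ci = std::min(gx - 1, std::max(0, (int)((x - bb[0]) / hx)));
    cj = std::min(gy - 1, std::max(0, (int)((y - bb[1]) / hy)));
    ck = std::min(gz - 1, std::max(0, (int)((z - bb[2]) / hz)));
  };
  for (int f = 0; f < nf; ++f) {
    double txmin = R_PosInf, txmax = R_NegInf, tymin = R_PosInf,
           tymax = R_NegInf, tzmin = R_PosInf, tzmax = R_NegInf;
    for (int v = 0; v < 3; ++v) {
      const int idx = F(f, v);
      txmin = std::min(txmin, V(idx, 0)); txmax = std::max(txmax, V(idx, 0));
      tymin = std::min(tymin, V(idx, 1)); tymax = std::max(tymax, V(idx, 1));
      tzmin = std::min(tzmin, V(idx, 2)); tzmax = std::max(tzmax, V(idx, 2));
    }
    int i0, j0, k0, i1, j1, k1;
    cell_of(txmin, tymin, tzmin, i0, j0, k0);
    cell_of(txmax, tymax, tzmax, i1, j1, k1);
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j)
        for (int k = k0; k <= k1; ++k)
          cells[(size_t)i + (size_t)gx * (j + (size_t)gy * k)].push_back(f);
  }

  NumericMatrix cp(nq, 3), nrm(nq, 3);
  NumericVector dist(nq);
  IntegerVector face(nq);
  // ring-distance lower bound: smallest cell pitch among non-degenerate
  // axes (a flat mesh collapses one axis to a single cell)
  double cellmin = R_PosInf;
  if (gx > 1) cellmin = std::min(cellmin, hx);
  if (gy > 1) cellmin = std::min(cellmin, hy);
  if (gz > 1) cellmin = std::min(cellmin, hz);
  if (!R_finite(cellmin)) cellmin = 1.0;
  const int ring_cap = gx + gy + gz + 2;

  for (int q = 0; q < nq; ++q) {
    Vec3 p{Q(q, 0), Q(q, 1), Q(q, 2)};
    int ci, cj, ck;
    cell_of(p.x, p.y, p.z, ci, cj, ck);
    double best = R_PosInf;
    Vec3 bestp{0, 0, 0};
    int bestf = -1;
    const int rmax = std::min((int)std::ceil(maxRadius / cellmin) + 1,
                              ring_cap);
    for (int r = 0; r <= rmax; ++r) {
      if (bestf >= 0 && best <= (r - 1) * cellmin) break;
      if (r > 0 && (r - 1) * cellmin > maxRadius) break;
      for (int i = std::max(0, ci - r); i <= std::min(gx - 1, ci + r); ++i)
        for (int j = std::max(0, cj - r); j <= std::min(gy - 1, cj + r); ++j)
          for (int k = std::max(0, ck - r); k <= std::min(gz - 1, ck + r); ++k) {
            if (std::max(std::abs(i - ci),
                         std::max(std::abs(j - cj), std::abs(k - ck))) != r)
              continue;  // shell only
            const std::vector<int> &lst =
                cells[(size_t)i + (size_t)gx * (j + (size_t)gy * k)];
            for (int f : lst) {
              Vec3 a{V(F(f,0),0), V(F(f,0),1), V(F(f,0),2)};
              Vec3 b{V(F(f,1),0), V(F(f,1),1), V(F(f,1),2)};
              Vec3 c{V(F(f,2),0), V(F(f,2),1), V(F(f,2),2)};
              Vec3 cpt = closest_on_triangle(p, a, b, c);
              Vec3 d = vsub(p, cpt);
              const double dd = std::sqrt(vdot(d, d));
              if (dd < best) { best = dd; bestp = cpt; bestf = f; }
            }
          }
    }
    if (bestf >= 0 && best <= maxRadius) {
      cp(q, 0) = bestp.x; cp(q, 1) = bestp.y; cp(q, 2) = bestp.z;
      Vec3 a{V(F(bestf,0),0), V(F(bestf,0),1), V(F(bestf,0),2)};
      Vec3 b{V(F(bestf,1),0), V(F(bestf,1),1), V(F(bestf,1),2)};
      Vec3 c{V(F(bestf,2),0), V(F(bestf,2),1), V(F(bestf,2),2)};
      Vec3 n = vcross(vsub(b, a), vsub(c, a));
      const double nn = std::sqrt(vdot(n, n));
      if (nn > 0) n = vscale(n, 1.0 / nn);
      nrm(q, 0) = n.x; nrm(q, 1) = n.y; nrm(q, 2) = n.z;
      dist[q] = best;
      face[q] = bestf + 1;
    } else {
      cp(q, 0) = NA_REAL; cp(q, 1) = NA_REAL; cp(q, 2) = NA_REAL;
      nrm(q, 0) = NA_REAL; nrm(q, 1) = NA_REAL; nrm(q, 2) = NA_REAL;
      dist[q] = NA_REAL;
      face[q] = NA_INTEGER;
    }
  }
  return List::create(_["points"] = cp, _["normals"] = nrm,
                      _["distance"] = dist, _["face"] = face);
}
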