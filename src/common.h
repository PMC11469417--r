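#ifndef RTCBCT_COMMON_H
#define RTCBCT_COMMON_H

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>

// Volume layout: column-major R array, dim (nx, ny, nz); linear index
// ix + nx*(iy + ny*iz). World position of voxel center = origin + index*spacing.
// Axes: x = left-right, y = anterior-posterior, z = superior-inferior.
// Projection frame layout: R matrix dim (n_v, n_u); linear index iv + n_v*iu.

struct Grid {
  int nx, ny, nz;
  double sx, sy, sz;   // spacing (mm)
  double ox, oy, oz;   // world coords of voxel (0,0,0) center (mm)
  Grid(const Rcpp::IntegerVector& dims, const Rcpp::NumericVector& spacing,
       const Rcpp::NumericVector& origin) {
    nx = dims[0]; ny = dims[1]; nz = dims[2];
    sx = spacing[0]; sy = spacing[1]; sz = spacing[2];
    ox = origin[0]; oy = origin[1]; oz = origin[2];
  }
  inline long n() const { return (long)nx * ny * nz; }
  inline long idx(int ix, int iy, int iz) const {
    return (long)ix + (long)nx * ((long)iy + (long)ny * iz);
  }
};

// Clamped trilinear sample of a scalar volume at continuous voxel index
// (cx, cy, cz). Indices are clamped to [0, n-1] (border replication).
inline double trilerp(const double* v, const Grid& g,
                      double cx, double cy, double cz) {
  if (cx < 0) cx = 0; if (cx > g.nx - 1) cx = g.nx - 1;
  if (cy < 0) cy = 0; if (cy > g.ny - 1) cy = g.ny - 1;
  if (cz < 0) cz = 0; if (cz > g.nz - 1) cz = g.nz - 1;
  int i0 = (int)std::floor(cx); if (i0 > g.nx - 2) i0 = g.nx >= 2 ? g.nx - 2 : 0;
  int j0 = (int)std::floor(cy); if (j0 > g.ny - 2) j0 = g.ny >= 2 ? g.ny - 2 : 0;
  int k0 = (int)std::floor(cz); if (k0 > g.nz - 2) k0 = g.nz >= 2 ? g.nz - 2 : 0;
  double fx = cx - i0, fy = cy - j0, fz = cz - k0;
  int i1 = g.nx >= 2 ? i0 + 1 : i0, j1 = g.ny >= 2 ? j0 + 1 : j0,
      k1 = g.nz >= 2 ? k0 + 1 : k0;
  // weight-product form: exact at integer offsets (zero-displacement warps
  // reproduce the input bit-for-bit) and identical to the adjoint's weights
  double gx1 = 1 - fx, gy1 = 1 - fy, gz1 = 1 - fz;
  double acc = 0.0;
  if (gx1 * gy1 * gz1 != 0) acc += gx1 * gy1 * gz1 * v[g.idx(i0, j0, k0)];
  if (fx  * gy1 * gz1 != 0) acc += fx  * gy1 * gz1 * v[g.idx(i1, j0, k0)];
  if (gx1 * fy  * gz1 != 0) acc += gx1 * fy  * gz1 * v[g.idx(i0, j1, k0)];
  if (fx  * fy  * gz1 != 0) acc += fx  * fy  * gz1 * v[g.idx(i1, j1, k0)];
  if (gx1 * gy1 * fz  != 0) acc += gx1 * gy1 * fz  * v[g.idx(i0, j0, k1)];
  if (fx  * gy1 * fz  != 0) acc += fx  * gy1 * fz  * v[g.idx(i1, j0, k1)];
  if (gx1 * fy  * fz  != 0) acc += gx1 * fy  * fz  * v[g.idx(i0, j1, k1)];
  if (fx  * fy  * fz  != 0) acc += fx  * fy  * fz  * v[g.idx(i1, j1, k1)];
  return acc;
}

struct ConeGeom {
  double sad, sdd, du, dv, off_u;
  int n_u, n_v;
  ConeGeom(double sad_, double sdd_, int nu_, int nv_, double du_, double dv_,
           double off_) : sad(sad_), sdd(sdd_), du(du_), dv(dv_), off_u(off_),
           n_u(nu_), n_v(nv_) {}
};

// Gantry angle convention: degrees, counter-clockwise about +z; at 0 degrees
// the source sits on the +y axis.
inline void source_frame(double angle_deg, double s[3], double uhat[3],
                         double vhat[3]) {
  double a = angle_deg * M_PI / 180.0;
  double sn = std::sin(a), cs = std::cos(a);
  s[0] = -sn; s[1] = cs; s[2] = 0.0;       // unit vector isocenter -> source
  uhat[0] = cs; uhat[1] = sn; uhat[2] = 0.0;
  vhat[0] = 0.0; vhat[1] = 0.0; vhat[2] = 1.0;
}

#endif
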