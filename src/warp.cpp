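#include "common.h"
using namespace Rcpp;

// Volume warping under the pull-back convention out(x) = in(x + d(x)),
// trilinear interpolation with border clamping, plus its backward pass and
// helpers for mask propagation and iterative DVF inversion.

// [[Rcpp::export]]
List cpp_warp_forward(NumericVector vol, NumericVector dvf,
                      IntegerVector dims, NumericVector spacing,
                      NumericVector origin) {
  Grid g(dims, spacing, origin);
  long n = g.n();
  const double* v = vol.begin();
  const double* dx = dvf.begin();
  const double* dy = dx + n;
  const double* dz = dy + n;
  NumericVector out(n);
  LogicalVector inside(n);
  long l = 0;
  for (int iz = 0; iz < g.nz; ++iz)
    for (int iy = 0; iy < g.ny; ++iy)
      for (int ix = 0; ix < g.nx; ++ix, ++l) {
        double cx = ix + dx[l] / g.sx;
        double cy = iy + dy[l] / g.sy;
        double cz = iz + dz[l] / g.sz;
        inside[l] = (cx >= 0 && cx <= g.nx - 1 && cy >= 0 && cy <= g.ny - 1 &&
                     cz >= 0 && cz <= g.nz - 1);
        out[l] = trilerp(v, g, cx, cy, cz);
      }
  return List::create(_["data"] = out, _["inside"] = inside);
}

// Backward pass: given dL/dout, returns dL/dvol (scatter through the
// interpolation weights) and dL/ddvf (image-gradient chain rule, in 1/mm).
// Clamped axes get zero displacement gradient.
// [[Rcpp::export]]
List cpp_warp_backward(NumericVector vol, NumericVector dvf,
                       NumericVector gout,
                       IntegerVector dims, NumericVector spacing,
                       NumericVector origin, bool need_gvol, bool need_gdvf) {
  Grid g(dims, spacing, origin);
  long n = g.n();
  const double* v = vol.begin();
  const double* dx = dvf.begin();
  const double* dy = dx + n;
  const double* dz = dy + n;
  const double* go = gout.begin();
  NumericVector gvol(need_gvol ? n : 0), gdvf(need_gdvf ? 3 * n : 0);
  double* gv = need_gvol ? gvol.begin() : nullptr;
  double* gdx = need_gdvf ? gdvf.begin() : nullptr;
  double* gdy = need_gdvf ? gdx + n : nullptr;
  double* gdz = need_gdvf ? gdy + n : nullptr;
  long l = 0;
  for (int iz = 0; iz < g.nz; ++iz)
    for (int iy = 0; iy < g.ny; ++iy)
      for (int ix = 0; ix < g.nx; ++ix, ++l) {
        double gpix = go[l];
        if (gpix == 0.0) continue;
        double cx = ix + dx[l] / g.sx;
        double cy = iy + dy[l] / g.sy;
        double cz = iz + dz[l] / g.sz;
        bool clx = (cx < 0 || cx > g.nx - 1);
        bool cly = (cy < 0 || cy > g.ny - 1);
        bool clz = (cz < 0 || cz > g.nz - 1);
        if (cx < 0) cx = 0; if (cx > g.nx - 1) cx = g.nx - 1;
        if (cy < 0) cy = 0; if (cy > g.ny - 1) cy = g.ny - 1;
        if (cz < 0) cz = 0; if (cz > g.nz - 1) cz = g.nz - 1;
        int i0 = (int)std::floor(cx); if (i0 > g.nx - 2) i0 = g.nx >= 2 ? g.nx - 2 : 0;
        int j0 = (int)std::floor(cy); if (j0 > g.ny - 2) j0 = g.ny >= 2 ? g.ny - 2 : 0;
        int k0 = (int)std::floor(cz); if (k0 > g.nz - 2) k0 = g.nz >= 2 ? g.nz - 2 : 0;
        double fx = cx - i0, fy = cy - j0, fz = cz - k0;
        int i1 = g.nx >= 2 ? i0 + 1 : i0, j1 = g.ny >= 2 ? j0 + 1 : j0,
            k1 = g.nz >= 2 ? k0 + 1 : k0;
        double w000 = (1 - fx) * (1 - fy) * (1 - fz), w100 = fx * (1 - fy) * (1 - fz);
        double w010 = (1 - fx) * fy * (1 - fz), w110 = fx * fy * (1 - fz);
        double w001 = (1 - fx) * (1 - fy) * fz, w101 = fx * (1 - fy) * fz;
        double w011 = (1 - fx) * fy * fz, w111 = fx * fy * fz;
        if (need_gvol) {
          gv[g.idx(i0, j0, k0)] += gpix * w000;
          gv[g.idx(i1, j0, k0)] += gpix * w100;
          gv[g.idx(i0, j1, k0)] += gpix * w010;
          gv[g.idx(i1, j1, k0)] += gpix * w110;
          gv[g.idx(i0, j0, k1)] += gpix * w001;
          gv[g.idx(i1, j0, k1)] += gpix * w101;
          gv[g.idx(i0, j1, k1)] += gpix * w011;
          gv[g.idx(i1, j1, k1)] += gpix * w111;
        }
        if (need_gdvf) {
          double c000 = v[g.idx(i0, j0, k0)], c100 = v[g.idx(i1, j0, k0)];
          double c010 = v[g.idx(i0, j1, k0)], c110 = v[g.idx(i1, j1, k0)];
          double c001 = v[g.idx(i0, j0, k1)], c101 = v[g.idx(i1, j0, k1)];
          double c011 = v[g.idx(i0, j1, k1)], c111 = v[g.idx(i1, j1, k1)];
          if (!clx) {
            double d = (c100 - c000) * (1 - fy) * (1 - fz) +
                       (c110 - c010) * fy * (1 - fz) +
                       (c101 - c001) * (1 - fy) * fz + (c111 - c011) * fy * fz;
            gdx[l] += gpix * d / g.sx;
          }
          if (!cly) {
            double d = (c010 - c000) * (1 - fx) * (1 - fz) +
                       (c110 - c100) * fx * (1 - fz) +
                       (c011 - c001) * (1 - fx) * fz + (c111 - c101) * fx * fz;
            gdy[l] += gpix * d / g.sy;
          }
          if (!clz) {
            double d = (c001 - c000) * (1 - fx) * (1 - fy) +
                       (c101 - c100) * fx * (1 - fy) +
                       (c011 - c010) * (1 - fx) * fy + (c111 - c110) * fx * fy;
            gdz[l] += gpix * d / g.sz;
          }
        }
      }
  List res = List::create(_["gvol"] = gvol, _["gdvf"] = gdvf);
  return res;
}

// Nearest-neighbour warp for binary masks; samples outside the grid give 0.
// [[Rcpp::export]]
NumericVector cpp_warp_nearest(NumericVector vol, NumericVector dvf,
                               IntegerVector dims, NumericVector spacing,
                               NumericVector origin) {
  Grid g(dims, spacing, origin);
  long n = g.n();
  const double* v = vol.begin();
  const double* dx = dvf.begin();
  const double* dy = dx + n;
  const double* dz = dy + n;
  NumericVector out(n);
  long l = 0;
  for (int iz = 0; iz < g.nz; ++iz)
    for (int iy = 0; iy < g.ny; ++iy)
      for (int ix = 0; ix < g.nx; ++ix, ++l) {
        int i = (int)std::lround(ix + dx[l] / g.sx);
        int j = (int)std::lround(iy + dy[l] / g.sy);
        int k = (int)std::lround(iz + dz[l] / g.sz);
        if (i < 0 || i >= g.nx || j < 0 || j >= g.ny || k < 0 || k >= g.nz)
          out[l] = 0.0;
        else
          out[l] = v[g.idx(i, j, k)];
      }
  return out;
}

// shared-weight trilinear sample of all three components of a vector field
static inline void trilerp3(const double* dx, const double* dy,
                            const double* dz, const Grid& g,
                            double cx, double cy, double cz, double out[3]) {
  if (cx < 0) cx = 0; if (cx > g.nx - 1) cx = g.nx - 1;
  if (cy < 0) cy = 0; if (cy > g.ny - 1) cy = g.ny - 1;
  if (cz < 0) cz = 0; if (cz > g.nz - 1) cz = g.nz - 1;
  int i0 = (int)cx; if (i0 > g.nx - 2) i0 = g.nx >= 2 ? g.nx - 2 : 0;
  int j0 = (int)cy; if (j0 > g.ny - 2) j0 = g.ny >= 2 ? g.ny - 2 : 0;
  int k0 = (int)cz; if (k0 > g.nz - 2) k0 = g.nz >= 2 ? g.nz - 2 : 0;
  double fx = cx - i0, fy = cy - j0, fz = cz - k0;
  int i1 = g.nx >= 2 ? 1 : 0, j1 = g.ny >= 2 ? g.nx : 0,
      k1 = g.nz >= 2 ? g.nx * g.ny : 0;
  long base = g.idx(i0, j0, k0);
  double w000 = (1 - fx) * (1 - fy) * (1 - fz), w100 = fx * (1 - fy) * (1 - fz);
  double w010 = (1 - fx) * fy * (1 - fz), w110 = fx * fy * (1 - fz);
  double w001 = (1 - fx) * (1 - fy) * fz, w101 = fx * (1 - fy) * fz;
  double w011 = (1 - fx) * fy * fz, w111 = fx * fy * fz;
  const double* f[3] = {dx, dy, dz};
  for (int c = 0; c < 3; ++c) {
    const double* v = f[c] + base;
    out[c] = w000 * v[0] + w100 * v[i1] + w010 * v[j1] + w110 * v[i1 + j1] +
             w001 * v[k1] + w101 * v[i1 + k1] + w011 * v[j1 + k1] +
             w111 * v[i1 + j1 + k1];
  }
}

// Fixed-point DVF inversion: dinv_{n+1}(x) = -d(x + dinv_n(x)), dinv_0 = 0.
// [[Rcpp::export]]
NumericVector cpp_invert_dvf(NumericVector dvf, IntegerVector dims,
                             NumericVector spacing, NumericVector origin,
                             int iterations) {
  Grid g(dims, spacing, origin);
  long n = g.n();
  const double* dx = dvf.begin();
  const double* dy = dx + n;
  const double* dz = dy + n;
  NumericVector inv(3 * n);  // starts at zero
  NumericVector nxt(3 * n);
  for (int it = 0; it < iterations; ++it) {
    const double* ix_ = inv.begin();
    const double* iy_ = ix_ + n;
    const double* iz_ = iy_ + n;
    double s[3];
    long l = 0;
    for (int iz = 0; iz < g.nz; ++iz)
      for (int iy = 0; iy < g.ny; ++iy)
        for (int ix = 0; ix < g.nx; ++ix, ++l) {
          trilerp3(dx, dy, dz, g, ix + ix_[l] / g.sx, iy + iy_[l] / g.sy,
                   iz + iz_[l] / g.sz, s);
          nxt[l] = -s[0];
          nxt[l + n] = -s[1];
          nxt[l + 2 * n] = -s[2];
        }
    std::copy(nxt.begin(), nxt.end(), inv.begin());
  }
  return inv;
}

// Composition residual d(x + dinv(x)) + dinv(x), reported as per-voxel
// Euclidean norm (mm): the divergence diagnostic for invert_dvf.
// [[Rcpp::export]]
NumericVector cpp_inversion_residual(NumericVector dvf, NumericVector dinv,
                                     IntegerVector dims, NumericVector spacing,
                                     NumericVector origin) {
  Grid g(dims, spacing, origin);
  long n = g.n();
  const double* dx = dvf.begin();
  const double* dy = dx + n;
  const double* dz = dy + n;
  const double* ix_ = dinv.begin();
  const double* iy_ = ix_ + n;
  const double* iz_ = iy_ + n;
  NumericVector res(n);
  double s[3];
  long l = 0;
  for (int iz = 0; iz < g.nz; ++iz)
    for (int iy = 0; iy < g.ny; ++iy)
      for (int ix = 0; ix < g.nx; ++ix, ++l) {
        trilerp3(dx, dy, dz, g, ix + ix_[l] / g.sx, iy + iy_[l] / g.sy,
                 iz + iz_[l] / g.sz, s);
        double rx = s[0] + ix_[l], ry = s[1] + iy_[l], rz = s[2] + iz_[l];
        res[l] = std::sqrt(rx * rx + ry * ry + rz * rz);
      }
  return res;
}
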