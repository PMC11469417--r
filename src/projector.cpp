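#include "common.h"
using namespace Rcpp;

// Ray-driven cone-beam projector (Joseph-style fixed-step sampling of the
// trilinearly interpolated attenuation field). Linear in the volume values,
// with an exact adjoint used for gradient backpropagation.

struct Ray {
  double sx, sy, sz;   // source
  double dx, dy, dz;   // unit direction
  double t0, t1;       // entry/exit parameters (mm); t0 >= t1 means a miss
};

// Slab clipping of a ray against the volume's physical bounding box
// (voxel centers +- half a voxel).
static inline void clip_ray(Ray& r, const Grid& g) {
  double lo[3] = {g.ox - 0.5 * g.sx, g.oy - 0.5 * g.sy, g.oz - 0.5 * g.sz};
  double hi[3] = {g.ox + (g.nx - 0.5) * g.sx, g.oy + (g.ny - 0.5) * g.sy,
                  g.oz + (g.nz - 0.5) * g.sz};
  double p[3] = {r.sx, r.sy, r.sz};
  double d[3] = {r.dx, r.dy, r.dz};
  double tmin = 0.0, tmax = 1e30;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-12) {
      if (p[a] < lo[a] || p[a] > hi[a]) { r.t0 = 1.0; r.t1 = 0.0; return; }
    } else {
      double ta = (lo[a] - p[a]) / d[a], tb = (hi[a] - p[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > tmin) tmin = ta;
      if (tb < tmax) tmax = tb;
    }
  }
  r.t0 = tmin; r.t1 = tmax;
}

static inline Ray pixel_ray(const ConeGeom& cg, double angle, int iu, int iv) {
  double sdir[3], uh[3], vh[3];
  source_frame(angle, sdir, uh, vh);
  Ray r;
  r.sx = cg.sad * sdir[0]; r.sy = cg.sad * sdir[1]; r.sz = cg.sad * sdir[2];
  double u = cg.off_u + (iu - (cg.n_u - 1) / 2.0) * cg.du;
  double v = (iv - (cg.n_v - 1) / 2.0) * cg.dv;
  double px = r.sx - cg.sdd * sdir[0] + u * uh[0] + v * vh[0];
  double py = r.sy - cg.sdd * sdir[1] + u * uh[1] + v * vh[1];
  double pz = r.sz - cg.sdd * sdir[2] + u * uh[2] + v * vh[2];
  double dx = px - r.sx, dy = py - r.sy, dz = pz - r.sz;
  double nrm = std::sqrt(dx * dx + dy * dy + dz * dz);
  r.dx = dx / nrm; r.dy = dy / nrm; r.dz = dz / nrm;
  return r;
}

// [[Rcpp::export]]
NumericMatrix cpp_forward_project(NumericVector vol, IntegerVector dims,
                                  NumericVector spacing, NumericVector origin,
                                  double sad, double sdd, int n_u, int n_v,
                                  double du, double dv, double off_u,
                                  double angle, double step) {
  Grid g(dims, spacing, origin);
  ConeGeom cg(sad, sdd, n_u, n_v, du, dv, off_u);
  const double* v = vol.begin();
  NumericMatrix out(n_v, n_u);
  for (int iu = 0; iu < n_u; ++iu) {
    for (int iv = 0; iv < n_v; ++iv) {
      Ray r = pixel_ray(cg, angle, iu, iv);
      clip_ray(r, g);
      if (r.t1 <= r.t0) { out(iv, iu) = 0.0; continue; }
      double len = r.t1 - r.t0;
      int m = (int)std::ceil(len / step);
      if (m < 1) m = 1;
      double h = len / m;
      if (g.nx < 2 || g.ny < 2 || g.nz < 2) {   // degenerate grids
        double acc = 0.0;
        for (int j = 0; j < m; ++j) {
          double t = r.t0 + (j + 0.5) * h;
          acc += trilerp(v, g, (r.sx + t * r.dx - g.ox) / g.sx,
                         (r.sy + t * r.dy - g.oy) / g.sy,
                         (r.sz + t * r.dz - g.oz) / g.sz);
        }
        out(iv, iu) = acc * h;
        continue;
      }
      // march in continuous index space (no per-sample divisions)
      double t0h = r.t0 + 0.5 * h;
      double cx = (r.sx + t0h * r.dx - g.ox) / g.sx;
      double cy = (r.sy + t0h * r.dy - g.oy) / g.sy;
      double cz = (r.sz + t0h * r.dz - g.oz) / g.sz;
      double hx = h * r.dx / g.sx, hy = h * r.dy / g.sy, hz = h * r.dz / g.sz;
      double acc = 0.0;
      for (int j = 0; j < m; ++j, cx += hx, cy += hy, cz += hz) {
        double px = cx < 0 ? 0 : (cx > g.nx - 1 ? g.nx - 1 : cx);
        double py = cy < 0 ? 0 : (cy > g.ny - 1 ? g.ny - 1 : cy);
        double pz = cz < 0 ? 0 : (cz > g.nz - 1 ? g.nz - 1 : cz);
        int i0 = (int)px; if (i0 > g.nx - 2) i0 = g.nx - 2;
        int j0 = (int)py; if (j0 > g.ny - 2) j0 = g.ny - 2;
        int k0 = (int)pz; if (k0 > g.nz - 2) k0 = g.nz - 2;
        double fx = px - i0, fy = py - j0, fz = pz - k0;
        const double* p000 = v + g.idx(i0, j0, k0);
        long sy = g.nx, sz = (long)g.nx * g.ny;
        double c00 = p000[0] + fx * (p000[1] - p000[0]);
        double c10 = p000[sy] + fx * (p000[sy + 1] - p000[sy]);
        double c01 = p000[sz] + fx * (p000[sz + 1] - p000[sz]);
        double c11 = p000[sz + sy] + fx * (p000[sz + sy + 1] - p000[sz + sy]);
        double c0 = c00 + fy * (c10 - c00);
        double c1 = c01 + fy * (c11 - c01);
        acc += c0 + fz * (c1 - c0);
      }
      out(iv, iu) = acc * h;
    }
  }
  return out;
}

// Adjoint of cpp_forward_project: scatter the projection-domain gradient back
// into the volume along exactly the same sampling pattern.
// [[Rcpp::export]]
NumericVector cpp_backproject_grad(NumericMatrix gproj, IntegerVector dims,
                                   NumericVector spacing, NumericVector origin,
                                   double sad, double sdd, int n_u, int n_v,
                                   double du, double dv, double off_u,
                                   double angle, double step) {
  Grid g(dims, spacing, origin);
  ConeGeom cg(sad, sdd, n_u, n_v, du, dv, off_u);
  NumericVector gvol(g.n());
  double* gv = gvol.begin();
  for (int iu = 0; iu < n_u; ++iu) {
    for (int iv = 0; iv < n_v; ++iv) {
      double gpix = gproj(iv, iu);
      if (gpix == 0.0) continue;
      Ray r = pixel_ray(cg, angle, iu, iv);
      clip_ray(r, g);
      if (r.t1 <= r.t0) continue;
      double len = r.t1 - r.t0;
      int m = (int)std::ceil(len / step);
      if (m < 1) m = 1;
      double h = len / m;
      double w = gpix * h;
      double t0h = r.t0 + 0.5 * h;
      double ccx = (r.sx + t0h * r.dx - g.ox) / g.sx;
      double ccy = (r.sy + t0h * r.dy - g.oy) / g.sy;
      double ccz = (r.sz + t0h * r.dz - g.oz) / g.sz;
      double hx = h * r.dx / g.sx, hy = h * r.dy / g.sy, hz = h * r.dz / g.sz;
      for (int j = 0; j < m; ++j, ccx += hx, ccy += hy, ccz += hz) {
        double cx = ccx, cy = ccy, cz = ccz;
        if (cx < 0) cx = 0; if (cx > g.nx - 1) cx = g.nx - 1;
        if (cy < 0) cy = 0; if (cy > g.ny - 1) cy = g.ny - 1;
        if (cz < 0) cz = 0; if (cz > g.nz - 1) cz = g.nz - 1;
        int i0 = (int)std::floor(cx); if (i0 > g.nx - 2) i0 = g.nx >= 2 ? g.nx - 2 : 0;
        int j0 = (int)std::floor(cy); if (j0 > g.ny - 2) j0 = g.ny >= 2 ? g.ny - 2 : 0;
        int k0 = (int)std::floor(cz); if (k0 > g.nz - 2) k0 = g.nz >= 2 ? g.nz - 2 : 0;
        double fx = cx - i0, fy = cy - j0, fz = cz - k0;
        int i1 = g.nx >= 2 ? i0 + 1 : i0, j1 = g.ny >= 2 ? j0 + 1 : j0,
            k1 = g.nz >= 2 ? k0 + 1 : k0;
        gv[g.idx(i0, j0, k0)] += w * (1 - fx) * (1 - fy) * (1 - fz);
        gv[g.idx(i1, j0, k0)] += w * fx * (1 - fy) * (1 - fz);
        gv[g.idx(i0, j1, k0)] += w * (1 - fx) * fy * (1 - fz);
        gv[g.idx(i1, j1, k0)] += w * fx * fy * (1 - fz);
        gv[g.idx(i0, j0, k1)] += w * (1 - fx) * (1 - fy) * fz;
        gv[g.idx(i1, j0, k1)] += w * fx * (1 - fy) * fz;
        gv[g.idx(i0, j1, k1)] += w * (1 - fx) * fy * fz;
        gv[g.idx(i1, j1, k1)] += w * fx * fy * fz;
      }
    }
  }
  return gvol;
}

// Siddon exact radiological path integrator: test oracle for the Joseph
// projector. Treats each voxel as a constant-attenuation box with faces at
// center +- half spacing and accumulates exact intersection lengths.
// [[Rcpp::export]]
NumericMatrix cpp_siddon_project(NumericVector vol, IntegerVector dims,
                                 NumericVector spacing, NumericVector origin,
                                 double sad, double sdd, int n_u, int n_v,
                                 double du, double dv, double off_u,
                                 double angle) {
  Grid g(dims, spacing, origin);
  ConeGeom cg(sad, sdd, n_u, n_v, du, dv, off_u);
  const double* v = vol.begin();
  NumericMatrix out(n_v, n_u);
  double sp[3] = {g.sx, g.sy, g.sz};
  double lo[3] = {g.ox - 0.5 * g.sx, g.oy - 0.5 * g.sy, g.oz - 0.5 * g.sz};
  int nn[3] = {g.nx, g.ny, g.nz};
  for (int iu = 0; iu < n_u; ++iu) {
    for (int iv = 0; iv < n_v; ++iv) {
      Ray r = pixel_ray(cg, angle, iu, iv);
      clip_ray(r, g);
      if (r.t1 <= r.t0 + 1e-12) { out(iv, iu) = 0.0; continue; }
      double p0[3] = {r.sx, r.sy, r.sz};
      double dir[3] = {r.dx, r.dy, r.dz};
      // current voxel at entry point (nudged inside)
      double t = r.t0 + 1e-9;
      int idx3[3];
      for (int a = 0; a < 3; ++a) {
        int i = (int)std::floor((p0[a] + t * dir[a] - lo[a]) / sp[a]);
        if (i < 0) i = 0; if (i > nn[a] - 1) i = nn[a] - 1;
        idx3[a] = i;
      }
      double tnext[3]; int istep[3];
      for (int a = 0; a < 3; ++a) {
        if (dir[a] > 1e-12) {
          istep[a] = 1;
          tnext[a] = ((lo[a] + (idx3[a] + 1) * sp[a]) - p0[a]) / dir[a];
        } else if (dir[a] < -1e-12) {
          istep[a] = -1;
          tnext[a] = ((lo[a] + idx3[a] * sp[a]) - p0[a]) / dir[a];
        } else { istep[a] = 0; tnext[a] = 1e30; }
      }
      double acc = 0.0, tcur = r.t0;
      while (tcur < r.t1 - 1e-12) {
        int a = 0;
        if (tnext[1] < tnext[a]) a = 1;
        if (tnext[2] < tnext[a]) a = 2;
        double tstop = std::min(tnext[a], r.t1);
        acc += (tstop - tcur) * v[g.idx(idx3[0], idx3[1], idx3[2])];
        tcur = tstop;
        if (tstop >= r.t1 - 1e-12) break;
        idx3[a] += istep[a];
        if (idx3[a] < 0 || idx3[a] >= nn[a]) break;
        tnext[a] += sp[a] / std::fabs(dir[a]);
      }
      out(iv, iu) = acc;
    }
  }
  return out;
}
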