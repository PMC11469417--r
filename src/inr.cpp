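#include "common.h"
using namespace Rcpp;

// Multiresolution hash encoding of voxel-center coordinates (instant-ngp
// style): per level a trilinearly interpolated feature grid, stored densely
// while (N+1)^3 fits the table and hashed (xor of per-axis primes, table
// size a power of two) beyond. The MLP head lives in R on top of the
// feature matrix produced here, so the heavy lifting is gathers here and
// BLAS there. cpp_inr_feature_adjoint scatters feature-matrix gradients
// back into the tables.

static const uint32_t PRIME2 = 2654435761u;
static const uint32_t PRIME3 = 805459861u;

struct EncCfg {
  int L, F, T;
  std::vector<int> res;
  double bmin[3], bmax[3];
};

static EncCfg enc_cfg(List cfg) {
  EncCfg c;
  c.L = as<int>(cfg["n_levels"]);
  c.F = as<int>(cfg["n_features"]);
  c.T = as<int>(cfg["table_size"]);
  IntegerVector r = cfg["resolutions"];
  c.res.assign(r.begin(), r.end());
  NumericVector bmin = cfg["bounds_min"], bmax = cfg["bounds_max"];
  for (int a = 0; a < 3; ++a) { c.bmin[a] = bmin[a]; c.bmax[a] = bmax[a]; }
  if ((c.T & (c.T - 1)) != 0) stop("table_size must be a power of two");
  return c;
}

// per-axis lookup tables for one level on a regular grid
struct AxisTab {
  std::vector<int> i0;         // lower corner index
  std::vector<double> f;       // fraction
  std::vector<uint32_t> h0, h1;  // hash contributions of corner 0/1
};

static AxisTab axis_tab(int n, double o, double s, double b0, double b1,
                        int N, uint32_t prime, bool dense, int T) {
  AxisTab t;
  t.i0.resize(n); t.f.resize(n); t.h0.resize(n); t.h1.resize(n);
  for (int i = 0; i < n; ++i) {
    double q = (o + i * s - b0) / (b1 - b0);
    if (q < 0) q = 0;
    if (q > 1) q = 1;
    double p = q * N;
    int i0 = (int)p; if (i0 > N - 1) i0 = N - 1;
    t.i0[i] = i0;
    t.f[i] = p - i0;
    if (dense) { t.h0[i] = (uint32_t)i0; t.h1[i] = (uint32_t)(i0 + 1); }
    else {
      t.h0[i] = (uint32_t)i0 * prime;
      t.h1[i] = (uint32_t)(i0 + 1) * prime;
    }
  }
  return t;
}

// Compute the feature matrix (np x L*F, column-major) for the voxel centers
// of a grid (idx empty) or a 0-based subset of linear voxel indices.
// Optionally accumulate the adjoint instead: when gfeat is non-NULL,
// scatter gfeat (np x L*F) into gtables and return nothing useful.
static void encode_core(const EncCfg& c, const double* tables,
                        const Grid& g, const int* idx, long np,
                        double* feat, const double* gfeat, double* gtables) {
  uint32_t mask = (uint32_t)(c.T - 1);
  for (int l = 0; l < c.L; ++l) {
    int N = c.res[l];
    long n1 = (long)N + 1;
    bool dense = n1 * n1 * n1 <= (long)c.T;
    AxisTab tx = axis_tab(g.nx, g.ox, g.sx, c.bmin[0], c.bmax[0], N,
                          1u, dense, c.T);
    AxisTab ty = axis_tab(g.ny, g.oy, g.sy, c.bmin[1], c.bmax[1], N,
                          PRIME2, dense, c.T);
    AxisTab tz = axis_tab(g.nz, g.oz, g.sz, c.bmin[2], c.bmax[2], N,
                          PRIME3, dense, c.T);
    const double* tab = tables + (long)l * c.T * c.F;
    double* gtab = gtables ? gtables + (long)l * c.T * c.F : nullptr;
    int F = c.F;
    // full-grid pass avoids the per-voxel index arithmetic of the subset
    // path by iterating the grid axes directly
    int ix = 0, iy = 0, iz = 0;
    for (long p = 0; p < np; ++p) {
      if (idx) {
        long lin = (long)idx[p];
        ix = (int)(lin % g.nx);
        iy = (int)((lin / g.nx) % g.ny);
        iz = (int)(lin / ((long)g.nx * g.ny));
      }
      double fx = tx.f[ix], fy = ty.f[iy], fz = tz.f[iz];
      uint32_t e[8];
      if (dense) {
        uint32_t x0 = tx.h0[ix], x1 = tx.h1[ix];
        uint32_t y0 = ty.h0[iy] * (uint32_t)n1, y1 = ty.h1[iy] * (uint32_t)n1;
        uint32_t z0 = tz.h0[iz] * (uint32_t)(n1 * n1),
                 z1 = tz.h1[iz] * (uint32_t)(n1 * n1);
        e[0] = x0 + y0 + z0; e[1] = x1 + y0 + z0;
        e[2] = x0 + y1 + z0; e[3] = x1 + y1 + z0;
        e[4] = x0 + y0 + z1; e[5] = x1 + y0 + z1;
        e[6] = x0 + y1 + z1; e[7] = x1 + y1 + z1;
      } else {
        uint32_t x0 = tx.h0[ix], x1 = tx.h1[ix];
        uint32_t y0 = ty.h0[iy], y1 = ty.h1[iy];
        uint32_t z0 = tz.h0[iz], z1 = tz.h1[iz];
        e[0] = (x0 ^ y0 ^ z0) & mask; e[1] = (x1 ^ y0 ^ z0) & mask;
        e[2] = (x0 ^ y1 ^ z0) & mask; e[3] = (x1 ^ y1 ^ z0) & mask;
        e[4] = (x0 ^ y0 ^ z1) & mask; e[5] = (x1 ^ y0 ^ z1) & mask;
        e[6] = (x0 ^ y1 ^ z1) & mask; e[7] = (x1 ^ y1 ^ z1) & mask;
      }
      double w[8];
      double gx1 = 1 - fx, gy1 = 1 - fy, gz1 = 1 - fz;
      w[0] = gx1 * gy1 * gz1; w[1] = fx * gy1 * gz1;
      w[2] = gx1 * fy * gz1;  w[3] = fx * fy * gz1;
      w[4] = gx1 * gy1 * fz;  w[5] = fx * gy1 * fz;
      w[6] = gx1 * fy * fz;   w[7] = fx * fy * fz;
      if (!gfeat) {
        for (int f = 0; f < F; ++f) {
          double acc = 0.0;
          for (int q = 0; q < 8; ++q) acc += w[q] * tab[(long)e[q] * F + f];
          feat[((long)(l * F + f)) * np + p] = acc;
        }
      } else {
        for (int f = 0; f < F; ++f) {
          double gv = gfeat[((long)(l * F + f)) * np + p];
          if (gv == 0.0) continue;
          for (int q = 0; q < 8; ++q) gtab[(long)e[q] * F + f] += w[q] * gv;
        }
      }
      if (!idx && ++ix == g.nx) {
        ix = 0;
        if (++iy == g.ny) { iy = 0; ++iz; }
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_inr_features(NumericVector tables, List cfg,
                               IntegerVector dims, NumericVector spacing,
                               NumericVector origin, IntegerVector idx) {
  EncCfg c = enc_cfg(cfg);
  Grid g(dims, spacing, origin);
  bool all = idx.size() == 0;
  long np = all ? g.n() : idx.size();
  NumericMatrix F(np, c.L * c.F);
  encode_core(c, tables.begin(), g, all ? nullptr : idx.begin(), np,
              F.begin(), nullptr, nullptr);
  return F;
}

// [[Rcpp::export]]
NumericVector cpp_inr_feature_adjoint(NumericMatrix gfeat,
                                      NumericVector tables, List cfg,
                                      IntegerVector dims,
                                      NumericVector spacing,
                                      NumericVector origin,
                                      IntegerVector idx) {
  EncCfg c = enc_cfg(cfg);
  Grid g(dims, spacing, origin);
  bool all = idx.size() == 0;
  long np = all ? g.n() : idx.size();
  if (gfeat.nrow() != np || gfeat.ncol() != c.L * c.F)
    stop("gradient matrix has the wrong shape");
  NumericVector gtab((long)c.L * c.T * c.F);
  encode_core(c, tables.begin(), g, all ? nullptr : idx.begin(), np,
              nullptr, gfeat.begin(), gtab.begin());
  return gtab;
}
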