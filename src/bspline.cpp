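#include "common.h"
using namespace Rcpp;

// Dense evaluation of a uniform cubic B-spline coefficient grid on a volume
// grid, via separable tensor-product contractions, plus the exact adjoint
// (dense-field gradient -> coefficient gradient). Control point j of an axis
// with nc points and knot spacing delta sits at world coordinate
// x0 + (j - 1) * delta; the patch [x0, x0 + (nc - 3) * delta] has full
// support.

static void axis_weights(int nvox, double vox0, double voxsp,
                         double x0, double delta, int nc,
                         std::vector<int>& base, std::vector<double>& w) {
  base.resize(nvox);
  w.resize(4 * nvox);
  for (int i = 0; i < nvox; ++i) {
    double gpos = (vox0 + i * voxsp - x0) / delta;
    if (gpos < 0) gpos = 0;
    if (gpos > nc - 3) gpos = nc - 3;
    int b = (int)std::floor(gpos);
    if (b > nc - 4) b = nc - 4;
    double u = gpos - b;
    double u2 = u * u, u3 = u2 * u;
    base[i] = b;
    w[4 * i + 0] = (1 - 3 * u + 3 * u2 - u3) / 6.0;
    w[4 * i + 1] = (4 - 6 * u2 + 3 * u3) / 6.0;
    w[4 * i + 2] = (1 + 3 * u + 3 * u2 - 3 * u3) / 6.0;
    w[4 * i + 3] = u3 / 6.0;
  }
}

// [[Rcpp::export]]
NumericVector cpp_bspline_eval(NumericVector coef, IntegerVector ncdims,
                               IntegerVector dims, NumericVector spacing,
                               NumericVector origin,
                               NumericVector x0, NumericVector delta) {
  Grid g(dims, spacing, origin);
  int ncx = ncdims[0], ncy = ncdims[1], ncz = ncdims[2];
  std::vector<int> bx, by, bz;
  std::vector<double> wx, wy, wz;
  axis_weights(g.nx, g.ox, g.sx, x0[0], delta[0], ncx, bx, wx);
  axis_weights(g.ny, g.oy, g.sy, x0[1], delta[1], ncy, by, wy);
  axis_weights(g.nz, g.oz, g.sz, x0[2], delta[2], ncz, bz, wz);
  const double* C = coef.begin();
  // pass 1: contract x -> T1(nx, ncy, ncz)
  std::vector<double> T1((long)g.nx * ncy * ncz, 0.0);
  for (int cz = 0; cz < ncz; ++cz)
    for (int cy = 0; cy < ncy; ++cy) {
      const double* col = C + (long)ncx * (cy + (long)ncy * cz);
      double* t = T1.data() + (long)g.nx * (cy + (long)ncy * cz);
      for (int ix = 0; ix < g.nx; ++ix) {
        const double* ww = &wx[4 * ix];
        const double* cc = col + bx[ix];
        t[ix] = ww[0] * cc[0] + ww[1] * cc[1] + ww[2] * cc[2] + ww[3] * cc[3];
      }
    }
  // pass 2: contract y -> T2(nx, ny, ncz)
  std::vector<double> T2((long)g.nx * g.ny * ncz, 0.0);
  for (int cz = 0; cz < ncz; ++cz)
    for (int iy = 0; iy < g.ny; ++iy) {
      const double* ww = &wy[4 * iy];
      double* t2 = T2.data() + (long)g.nx * (iy + (long)g.ny * cz);
      for (int m = 0; m < 4; ++m) {
        const double* t1 = T1.data() + (long)g.nx * ((by[iy] + m) + (long)ncy * cz);
        double wm = ww[m];
        if (m == 0)
          for (int ix = 0; ix < g.nx; ++ix) t2[ix] = wm * t1[ix];
        else
          for (int ix = 0; ix < g.nx; ++ix) t2[ix] += wm * t1[ix];
      }
    }
  // pass 3: contract z -> out(nx, ny, nz)
  NumericVector out(g.n());
  double* O = out.begin();
  for (int iz = 0; iz < g.nz; ++iz) {
    const double* ww = &wz[4 * iz];
    double* o = O + (long)g.nx * g.ny * iz;
    for (int m = 0; m < 4; ++m) {
      const double* t2 = T2.data() + (long)g.nx * g.ny * (bz[iz] + m);
      double wm = ww[m];
      if (m == 0)
        for (long l = 0; l < (long)g.nx * g.ny; ++l) o[l] = wm * t2[l];
      else
        for (long l = 0; l < (long)g.nx * g.ny; ++l) o[l] += wm * t2[l];
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_bspline_adjoint(NumericVector gfield, IntegerVector ncdims,
                                  IntegerVector dims, NumericVector spacing,
                                  NumericVector origin,
                                  NumericVector x0, NumericVector delta) {
  Grid g(dims, spacing, origin);
  int ncx = ncdims[0], ncy = ncdims[1], ncz = ncdims[2];
  std::vector<int> bx, by, bz;
  std::vector<double> wx, wy, wz;
  axis_weights(g.nx, g.ox, g.sx, x0[0], delta[0], ncx, bx, wx);
  axis_weights(g.ny, g.oy, g.sy, x0[1], delta[1], ncy, by, wy);
  axis_weights(g.nz, g.oz, g.sz, x0[2], delta[2], ncz, bz, wz);
  const double* G = gfield.begin();
  // adjoint pass 1: contract z -> T2(nx, ny, ncz)
  std::vector<double> T2((long)g.nx * g.ny * ncz, 0.0);
  for (int iz = 0; iz < g.nz; ++iz) {
    const double* ww = &wz[4 * iz];
    const double* gsl = G + (long)g.nx * g.ny * iz;
    for (int m = 0; m < 4; ++m) {
      double* t2 = T2.data() + (long)g.nx * g.ny * (bz[iz] + m);
      double wm = ww[m];
      for (long l = 0; l < (long)g.nx * g.ny; ++l) t2[l] += wm * gsl[l];
    }
  }
  // adjoint pass 2: contract y -> T1(nx, ncy, ncz)
  std::vector<double> T1((long)g.nx * ncy * ncz, 0.0);
  for (int cz = 0; cz < ncz; ++cz)
    for (int iy = 0; iy < g.ny; ++iy) {
      const double* ww = &wy[4 * iy];
      const double* t2 = T2.data() + (long)g.nx * (iy + (long)g.ny * cz);
      for (int m = 0; m < 4; ++m) {
        double* t1 = T1.data() + (long)g.nx * ((by[iy] + m) + (long)ncy * cz);
        double wm = ww[m];
        for (int ix = 0; ix < g.nx; ++ix) t1[ix] += wm * t2[ix];
      }
    }
  // adjoint pass 3: contract x -> coef grad
  NumericVector gc((long)ncx * ncy * ncz);
  double* GC = gc.begin();
  for (int cz = 0; cz < ncz; ++cz)
    for (int cy = 0; cy < ncy; ++cy) {
      double* col = GC + (long)ncx * (cy + (long)ncy * cz);
      const double* t1 = T1.data() + (long)g.nx * (cy + (long)ncy * cz);
      for (int ix = 0; ix < g.nx; ++ix) {
        const double* ww = &wx[4 * ix];
        double* cc = col + bx[ix];
        double v = t1[ix];
        cc[0] += ww[0] * v; cc[1] += ww[1] * v;
        cc[2] += ww[2] * v; cc[3] += ww[3] * v;
      }
    }
  return gc;
}
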