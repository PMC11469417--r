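#include "common.h"
using namespace Rcpp;

// Feldkamp-Davis-Kress filtered backprojection for a circular cone-beam scan.
// Projections are post-log line integrals. Filtering is done on the virtual
// detector at the isocenter (physical coordinates divided by the
// magnification sdd/sad), with the exact discrete ramp kernel
//   h[0] = 1/(4 du'^2),  h[n odd] = -1/(pi^2 n^2 du'^2),  h[n even] = 0.

// [[Rcpp::export]]
NumericVector cpp_ramp_kernel(int n, double du) {
  NumericVector h(2 * n + 1);
  for (int k = -n; k <= n; ++k) {
    double val;
    if (k == 0) val = 1.0 / (4.0 * du * du);
    else if (k % 2 == 0) val = 0.0;
    else val = -1.0 / (M_PI * M_PI * (double)k * (double)k * du * du);
    h[k + n] = val;
  }
  return h;
}

// [[Rcpp::export]]
NumericVector cpp_fdk_reconstruct(NumericVector frames, IntegerVector fdims,
                                  NumericVector angles,
                                  IntegerVector dims, NumericVector spacing,
                                  NumericVector origin,
                                  double sad, double sdd,
                                  double du, double dv, double off_u) {
  int n_v = fdims[0], n_u = fdims[1], np = fdims[2];
  Grid g(dims, spacing, origin);
  double mag = sdd / sad;
  double duv = du / mag, dvv = dv / mag, offv = off_u / mag;  // virtual detector
  // ramp kernel
  std::vector<double> h(2 * n_u - 1);
  for (int k = -(n_u - 1); k <= n_u - 1; ++k) {
    double val;
    if (k == 0) val = 1.0 / (4.0 * duv * duv);
    else if (k % 2 == 0) val = 0.0;
    else val = -1.0 / (M_PI * M_PI * (double)k * (double)k * duv * duv);
    h[k + n_u - 1] = val;
  }
  // cosine-weight + ramp-filter every frame (rows along u)
  std::vector<double> filt((long)n_v * n_u * np);
  std::vector<double> wrow(n_u);
  for (int p = 0; p < np; ++p) {
    const double* fr = frames.begin() + (long)p * n_v * n_u;
    double* fo = filt.data() + (long)p * n_v * n_u;
    for (int iv = 0; iv < n_v; ++iv) {
      double vv = (iv - (n_v - 1) / 2.0) * dvv;
      for (int iu = 0; iu < n_u; ++iu) {
        double uu = offv + (iu - (n_u - 1) / 2.0) * duv;
        double w = sad / std::sqrt(sad * sad + uu * uu + vv * vv);
        wrow[iu] = w * fr[iv + (long)n_v * iu];
      }
      for (int iu = 0; iu < n_u; ++iu) {
        double acc = 0.0;
        for (int j = 0; j < n_u; ++j) acc += wrow[j] * h[iu - j + n_u - 1];
        fo[iv + (long)n_v * iu] = acc * duv;
      }
    }
  }
  // weighted backprojection
  NumericVector vol(g.n());
  double* out = vol.begin();
  double dbeta = 2.0 * M_PI / np;  // full-scan assumption; redundancy factor 1/2
  for (int p = 0; p < np; ++p) {
    double sdir[3], uh[3], vh[3];
    source_frame(angles[p], sdir, uh, vh);
    const double* fo = filt.data() + (long)p * n_v * n_u;
    for (int iz = 0; iz < g.nz; ++iz) {
      double z = g.oz + iz * g.sz;
      for (int iy = 0; iy < g.ny; ++iy) {
        double y = g.oy + iy * g.sy;
        for (int ix = 0; ix < g.nx; ++ix) {
          double x = g.ox + ix * g.sx;
          double U = sad - (x * sdir[0] + y * sdir[1] + z * sdir[2]);
          if (U < 1e-6) continue;
          double uu = (x * uh[0] + y * uh[1]) * sad / U;
          double vv = z * sad / U;
          double cu = (uu - offv) / duv + (n_u - 1) / 2.0;
          double cv = vv / dvv + (n_v - 1) / 2.0;
          if (cu < 0 || cu > n_u - 1 || cv < 0 || cv > n_v - 1) continue;
          int iu0 = (int)std::floor(cu); if (iu0 > n_u - 2) iu0 = n_u - 2;
          int iv0 = (int)std::floor(cv); if (iv0 > n_v - 2) iv0 = n_v - 2;
          double fu = cu - iu0, fv = cv - iv0;
          double q00 = fo[iv0 + (long)n_v * iu0];
          double q10 = fo[iv0 + (long)n_v * (iu0 + 1)];
          double q01 = fo[iv0 + 1 + (long)n_v * iu0];
          double q11 = fo[iv0 + 1 + (long)n_v * (iu0 + 1)];
          double q = (1 - fu) * ((1 - fv) * q00 + fv * q01) +
                     fu * ((1 - fv) * q10 + fv * q11);
          out[g.idx(ix, iy, iz)] += 0.5 * dbeta * (sad * sad / (U * U)) * q;
        }
      }
    }
  }
  return vol;
}
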