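#include "common.h"
using namespace Rcpp;

// Small fused kernels for the training hot path.

// Isotropic total variation (forward differences, zero across the far face):
// returns the exact loss mean(sqrt(g2)) and the gradient of
// mean(sqrt(g2 + eps^2)) in one pass over the volume.
// [[Rcpp::export]]
List cpp_tv_loss_grad(NumericVector vol, IntegerVector dims, double eps,
                      bool want_grad) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  const double* v = vol.begin();
  NumericVector grad(want_grad ? n : 0);
  double* g = want_grad ? grad.begin() : nullptr;
  double loss = 0.0;
  double e2 = eps * eps;
  long l = 0;
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix, ++l) {
        double dx = (ix < nx - 1) ? v[l + 1] - v[l] : 0.0;
        double dy = (iy < ny - 1) ? v[l + nx] - v[l] : 0.0;
        double dz = (iz < nz - 1) ? v[l + (long)nx * ny] - v[l] : 0.0;
        double g2 = dx * dx + dy * dy + dz * dz;
        loss += std::sqrt(g2);
        if (want_grad && g2 > 0) {
          double inv = 1.0 / std::sqrt(g2 + e2);
          double gx = dx * inv, gy = dy * inv, gz = dz * inv;
          g[l] -= gx + gy + gz;
          if (ix < nx - 1) g[l + 1] += gx;
          if (iy < ny - 1) g[l + nx] += gy;
          if (iz < nz - 1) g[l + (long)nx * ny] += gz;
        }
      }
  if (want_grad) for (long i = 0; i < n; ++i) g[i] /= n;
  return List::create(_["loss"] = loss / n, _["grad"] = grad);
}

// Z <- relu(Z + bias[col]) in place (Z is n x k column-major).
// [[Rcpp::export]]
void cpp_addbias_relu(NumericMatrix Z, NumericVector bias) {
  long n = Z.nrow();
  int k = Z.ncol();
  for (int c = 0; c < k; ++c) {
    double b = bias[c];
    double* z = &Z(0, c);
    for (long i = 0; i < n; ++i) {
      double t = z[i] + b;
      z[i] = t > 0 ? t : 0;
    }
  }
}

// G <- G * (A > 0) in place (ReLU backward gate).
// [[Rcpp::export]]
void cpp_relu_gate(NumericMatrix G, NumericMatrix A) {
  long n = (long)G.nrow() * G.ncol();
  double* g = G.begin();
  const double* a = A.begin();
  for (long i = 0; i < n; ++i)
    if (a[i] <= 0) g[i] = 0;
}

// softplus with overflow guard
// [[Rcpp::export]]
NumericVector cpp_softplus(NumericVector z) {
  NumericVector out(z.size());
  for (long i = 0; i < (long)z.size(); ++i)
    out[i] = z[i] > 30 ? z[i] : std::log1p(std::exp(z[i]));
  return out;
}

// g * sigmoid(z) (softplus backward)
// [[Rcpp::export]]
NumericVector cpp_mul_sigmoid(NumericVector g, NumericVector z) {
  NumericVector out(z.size());
  for (long i = 0; i < (long)z.size(); ++i)
    out[i] = g[i] / (1.0 + std::exp(-z[i]));
  return out;
}
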