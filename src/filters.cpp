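#include "common.h"
#include <queue>
using namespace Rcpp;

// Separable 3D Gaussian filter with border replication (used by the
// volumetric SSIM) and a 6-connected flood fill for tumor contouring.

// 1D convolution along one axis with border replication; lines are gathered
// into a padded scratch buffer so the inner loop is branch-free.
static void blur_axis(const std::vector<double>& in, std::vector<double>& out,
                      int nx, int ny, int nz, int axis,
                      const std::vector<double>& k) {
  int r = ((int)k.size() - 1) / 2;
  int n[3] = {nx, ny, nz};
  long stride[3] = {1, (long)nx, (long)nx * ny};
  long sa = stride[axis];
  int na = n[axis];
  // iterate over all lines along `axis`
  int ob = (axis == 0) ? 1 : 0;          // the two orthogonal axes
  int oc = (axis == 2) ? 1 : 2;
  std::vector<double> line(na + 2 * r);
  for (int c = 0; c < n[oc]; ++c)
    for (int b = 0; b < n[ob]; ++b) {
      long base = (long)b * stride[ob] + (long)c * stride[oc];
      for (int i = 0; i < na; ++i) line[r + i] = in[base + (long)i * sa];
      for (int i = 0; i < r; ++i) {
        line[i] = line[r];
        line[r + na + i] = line[r + na - 1];
      }
      for (int i = 0; i < na; ++i) {
        double acc = 0.0;
        const double* lp = line.data() + i;
        for (int j = 0; j < 2 * r + 1; ++j) acc += k[j] * lp[j];
        out[base + (long)i * sa] = acc;
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur3(NumericVector vol, IntegerVector dims,
                                 double sigma, int radius) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> k(2 * radius + 1);
  double s = 0;
  for (int j = -radius; j <= radius; ++j) {
    k[j + radius] = std::exp(-0.5 * j * j / (sigma * sigma));
    s += k[j + radius];
  }
  for (auto& v : k) v /= s;
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  blur_axis(a, b, nx, ny, nz, 0, k);
  blur_axis(b, a, nx, ny, nz, 1, k);
  blur_axis(a, b, nx, ny, nz, 2, k);
  return NumericVector(b.begin(), b.end());
}

// 6-connected component labels of a binary volume (0 = background).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  IntegerVector label(n);
  int cur = 0;
  std::queue<long> q;
  for (long seed = 0; seed < n; ++seed) {
    if (!mask[seed] || label[seed]) continue;
    ++cur;
    label[seed] = cur;
    q.push(seed);
    while (!q.empty()) {
      long l = q.front(); q.pop();
      int ix = (int)(l % nx), iy = (int)((l / nx) % ny),
          iz = (int)(l / ((long)nx * ny));
      const int dx[6] = {1, -1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, 1, -1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, 1, -1};
      for (int d = 0; d < 6; ++d) {
        int jx = ix + dx[d], jy = iy + dy[d], jz = iz + dz[d];
        if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
          continue;
        long m = (long)jx + (long)nx * (jy + (long)ny * jz);
        if (mask[m] && !label[m]) { label[m] = cur; q.push(m); }
      }
    }
  }
  return label;
}

// Largest 6-connected component of a binary volume.
// [[Rcpp::export]]
LogicalVector cpp_largest_component(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  std::vector<int> label(n, 0);
  int cur = 0;
  long best_size = 0;
  int best_label = 0;
  std::queue<long> q;
  for (long seed = 0; seed < n; ++seed) {
    if (!mask[seed] || label[seed]) continue;
    ++cur;
    long size = 0;
    label[seed] = cur;
    q.push(seed);
    while (!q.empty()) {
      long l = q.front(); q.pop();
      ++size;
      int ix = (int)(l % nx), iy = (int)((l / nx) % ny), iz = (int)(l / ((long)nx * ny));
      const int dx[6] = {1, -1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, 1, -1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, 1, -1};
      for (int d = 0; d < 6; ++d) {
        int jx = ix + dx[d], jy = iy + dy[d], jz = iz + dz[d];
        if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz) continue;
        long m = (long)jx + (long)nx * (jy + (long)ny * jz);
        if (mask[m] && !label[m]) { label[m] = cur; q.push(m); }
      }
    }
    if (size > best_size) { best_size = size; best_label = cur; }
  }
  LogicalVector out(n);
  for (long l = 0; l < n; ++l) out[l] = (label[l] == best_label && best_label > 0);
  return out;
}

// Trilinear up/down-sampling of a volume onto another grid (world-aligned),
// used for the high-resolution warm-start label.
// [[Rcpp::export]]
NumericVector cpp_resample_volume(NumericVector vol, IntegerVector dims,
                                  NumericVector spacing, NumericVector origin,
                                  IntegerVector dims2, NumericVector spacing2,
                                  NumericVector origin2) {
  Grid g(dims, spacing, origin);
  Grid g2(dims2, spacing2, origin2);
  const double* v = vol.begin();
  NumericVector out(g2.n());
  long l = 0;
  for (int iz = 0; iz < g2.nz; ++iz)
    for (int iy = 0; iy < g2.ny; ++iy)
      for (int ix = 0; ix < g2.nx; ++ix, ++l) {
        double cx = (g2.ox + ix * g2.sx - g.ox) / g.sx;
        double cy = (g2.oy + iy * g2.sy - g.oy) / g.sy;
        double cz = (g2.oz + iz * g2.sz - g.oz) / g.sz;
        out[l] = trilerp(v, g, cx, cy, cz);
      }
  return out;
}

// 6-connected binary erosion (iterated).
// [[Rcpp::export]]
LogicalVector cpp_erode6(LogicalVector mask, IntegerVector dims, int iters) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  std::vector<char> cur(mask.begin(), mask.end()), nxt(n);
  for (int it = 0; it < iters; ++it) {
    long l = 0;
    for (int iz = 0; iz < nz; ++iz)
      for (int iy = 0; iy < ny; ++iy)
        for (int ix = 0; ix < nx; ++ix, ++l) {
          bool keep = cur[l] &&
            ix > 0 && cur[l - 1] && ix < nx - 1 && cur[l + 1] &&
            iy > 0 && cur[l - nx] && iy < ny - 1 && cur[l + nx] &&
            iz > 0 && cur[l - (long)nx * ny] &&
            iz < nz - 1 && cur[l + (long)nx * ny];
          nxt[l] = keep;
        }
    cur.swap(nxt);
  }
  LogicalVector out(n);
  for (long i = 0; i < n; ++i) out[i] = cur[i] != 0;
  return out;
}

// 6-connected binary dilation (iterated), optionally constrained to stay
// inside a support mask (geodesic dilation).
// [[Rcpp::export]]
LogicalVector cpp_dilate6(LogicalVector mask, IntegerVector dims, int iters,
                          LogicalVector support) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  bool has_sup = support.size() == n;
  std::vector<char> cur(mask.begin(), mask.end()), nxt(n);
  for (int it = 0; it < iters; ++it) {
    long l = 0;
    for (int iz = 0; iz < nz; ++iz)
      for (int iy = 0; iy < ny; ++iy)
        for (int ix = 0; ix < nx; ++ix, ++l) {
          bool on = cur[l] ||
            (ix > 0 && cur[l - 1]) || (ix < nx - 1 && cur[l + 1]) ||
            (iy > 0 && cur[l - nx]) || (iy < ny - 1 && cur[l + nx]) ||
            (iz > 0 && cur[l - (long)nx * ny]) ||
            (iz < nz - 1 && cur[l + (long)nx * ny]);
          if (has_sup && !support[l]) on = false;
          nxt[l] = on;
        }
    cur.swap(nxt);
  }
  LogicalVector out(n);
  for (long i = 0; i < n; ++i) out[i] = cur[i] != 0;
  return out;
}
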