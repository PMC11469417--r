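#include "common.h"
using namespace Rcpp;

// Convolutional motion encoder: six 3x3 stride-2 convolutions with channel
// widths 2, 4, 8, 16, 32, 32, each followed by batch normalization and ReLU,
// then a flatten and a linear layer with nine outputs (the motion basis
// component scores). Hand-written forward/backward; batch norm uses batch
// statistics in training mode and running statistics in eval mode.
//
// Tensor layout: per sample b and channel c, a column-major (h fastest)
// H x W slab at offset (b*C + c)*H*W.
// Flat parameter layout: per conv layer [W (co,ci,3,3; index
// ((o*ci+i)*3+kh)*3+kw), b, gamma, beta] then [fc_W (9 x nflat row-major),
// fc_b (9)]. Running stats: per layer [mean(co), var(co)].

struct CnnCfg {
  std::vector<int> ch;      // conv output channels
  int H0, W0;
  std::vector<int> Hs, Ws;  // per-layer output sizes
  int nflat;
  std::vector<long> woff;   // per-layer offset into flat params
  long fcoff;
  long nparam;
  std::vector<long> soff;   // running-stat offsets
  long nstat;
};

static CnnCfg cnn_cfg(List cfg) {
  CnnCfg c;
  IntegerVector ch = cfg["channels"];
  c.ch.assign(ch.begin(), ch.end());
  c.H0 = as<int>(cfg["input_h"]);
  c.W0 = as<int>(cfg["input_w"]);
  int H = c.H0, W = c.W0;
  long off = 0, soff = 0;
  int ci = 1;
  for (size_t l = 0; l < c.ch.size(); ++l) {
    int co = c.ch[l];
    H = (H + 1) / 2; W = (W + 1) / 2;  // stride 2, pad 1, kernel 3
    c.Hs.push_back(H); c.Ws.push_back(W);
    c.woff.push_back(off);
    off += (long)co * ci * 9 + 3L * co;  // W, b, gamma, beta
    c.soff.push_back(soff);
    soff += 2L * co;
    ci = co;
  }
  c.nflat = c.ch.back() * H * W;
  c.fcoff = off;
  c.nparam = off + 9L * c.nflat + 9;
  c.nstat = soff;
  return c;
}

// [[Rcpp::export]]
long cpp_cnn_nparam(List cfg) { return cnn_cfg(cfg).nparam; }

// [[Rcpp::export]]
long cpp_cnn_nstat(List cfg) { return cnn_cfg(cfg).nstat; }

static void conv_forward(const double* in, double* out, const double* W,
                         const double* b, int B, int ci, int co,
                         int Hi, int Wi, int Ho, int Wo) {
  for (int bb = 0; bb < B; ++bb)
    for (int o = 0; o < co; ++o) {
      double* op = out + ((long)bb * co + o) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = b[o];
          int hi0 = 2 * ho - 1, wi0 = 2 * wo - 1;
          for (int i = 0; i < ci; ++i) {
            const double* ip = in + ((long)bb * ci + i) * Hi * Wi;
            const double* wk = W + ((long)o * ci + i) * 9;
            for (int kh = 0; kh < 3; ++kh) {
              int hi = hi0 + kh;
              if (hi < 0 || hi >= Hi) continue;
              for (int kw = 0; kw < 3; ++kw) {
                int wi = wi0 + kw;
                if (wi < 0 || wi >= Wi) continue;
                acc += wk[kh * 3 + kw] * ip[hi + (long)Hi * wi];
              }
            }
          }
          op[ho + (long)Ho * wo] = acc;
        }
    }
}

// [[Rcpp::export]]
List cpp_cnn_forward(NumericVector x, int B, NumericVector params,
                     NumericVector rstats, List cfg, bool train,
                     double momentum, double eps) {
  CnnCfg c = cnn_cfg(cfg);
  int nl = (int)c.ch.size();
  List cache(2 * nl + 1);
  NumericVector newstats = clone(rstats);
  std::vector<double> bmeans, bvars;  // per layer batch stats (train)
  NumericVector act = clone(x);       // current activations
  int Hi = c.H0, Wi = c.W0, ci = 1;
  NumericVector batch_stats(2L * 0);
  std::vector<NumericVector> zs(nl), as(nl);
  NumericVector bstat(c.nstat);
  for (int l = 0; l < nl; ++l) {
    int co = c.ch[l], Ho = c.Hs[l], Wo = c.Ws[l];
    const double* W = params.begin() + c.woff[l];
    const double* bb = W + (long)co * ci * 9;
    const double* gamma = bb + co;
    const double* beta = gamma + co;
    NumericVector z((long)B * co * Ho * Wo);
    conv_forward(act.begin(), z.begin(), W, bb, B, ci, co, Hi, Wi, Ho, Wo);
    // batch norm
    long m = (long)B * Ho * Wo;
    NumericVector a((long)B * co * Ho * Wo);
    for (int o = 0; o < co; ++o) {
      double mu, var;
      if (train) {
        double s = 0, s2 = 0;
        for (int b2 = 0; b2 < B; ++b2) {
          const double* zp = z.begin() + ((long)b2 * co + o) * Ho * Wo;
          for (long q = 0; q < (long)Ho * Wo; ++q) { s += zp[q]; s2 += zp[q] * zp[q]; }
        }
        mu = s / m;
        var = s2 / m - mu * mu;
        if (var < 0) var = 0;
        newstats[c.soff[l] + o] = (1 - momentum) * newstats[c.soff[l] + o] + momentum * mu;
        newstats[c.soff[l] + co + o] =
            (1 - momentum) * newstats[c.soff[l] + co + o] + momentum * var;
      } else {
        mu = rstats[c.soff[l] + o];
        var = rstats[c.soff[l] + co + o];
      }
      bstat[c.soff[l] + o] = mu;
      bstat[c.soff[l] + co + o] = var;
      double inv = 1.0 / std::sqrt(var + eps);
      for (int b2 = 0; b2 < B; ++b2) {
        const double* zp = z.begin() + ((long)b2 * co + o) * Ho * Wo;
        double* ap = a.begin() + ((long)b2 * co + o) * Ho * Wo;
        for (long q = 0; q < (long)Ho * Wo; ++q) {
          double y = gamma[o] * (zp[q] - mu) * inv + beta[o];
          ap[q] = y > 0 ? y : 0;  // ReLU
        }
      }
    }
    zs[l] = z; as[l] = a;
    act = a;
    Hi = Ho; Wi = Wo; ci = co;
  }
  // linear head
  const double* fcW = params.begin() + c.fcoff;
  const double* fcb = fcW + 9L * c.nflat;
  NumericMatrix scores(9, B);
  for (int b2 = 0; b2 < B; ++b2) {
    const double* ap = act.begin() + (long)b2 * c.nflat;
    for (int o = 0; o < 9; ++o) {
      const double* wr = fcW + (long)o * c.nflat;
      double acc = fcb[o];
      for (int i = 0; i < c.nflat; ++i) acc += wr[i] * ap[i];
      scores(o, b2) = acc;
    }
  }
  List zl(nl), al(nl);
  for (int l = 0; l < nl; ++l) { zl[l] = zs[l]; al[l] = as[l]; }
  return List::create(_["scores"] = scores, _["z"] = zl, _["a"] = al,
                      _["bstat"] = bstat, _["rstats"] = newstats);
}

// [[Rcpp::export]]
List cpp_cnn_backward(NumericVector x, int B, NumericVector params,
                      List cache, NumericMatrix gscores, List cfg,
                      bool train, double eps, bool need_ginput) {
  CnnCfg c = cnn_cfg(cfg);
  int nl = (int)c.ch.size();
  List zl = cache["z"], al = cache["a"];
  NumericVector bstat = cache["bstat"];
  NumericVector gparams(c.nparam);
  // linear head backward
  const double* fcW = params.begin() + c.fcoff;
  double* gfcW = gparams.begin() + c.fcoff;
  double* gfcb = gfcW + 9L * c.nflat;
  NumericVector alast = al[nl - 1];
  NumericVector ga((long)B * c.nflat);
  for (int b2 = 0; b2 < B; ++b2) {
    const double* ap = alast.begin() + (long)b2 * c.nflat;
    double* gap = ga.begin() + (long)b2 * c.nflat;
    for (int o = 0; o < 9; ++o) {
      double go = gscores(o, b2);
      if (go == 0.0) continue;
      gfcb[o] += go;
      const double* wr = fcW + (long)o * c.nflat;
      double* gwr = gfcW + (long)o * c.nflat;
      for (int i = 0; i < c.nflat; ++i) {
        gwr[i] += go * ap[i];
        gap[i] += go * wr[i];
      }
    }
  }
  // conv stack backward
  for (int l = nl - 1; l >= 0; --l) {
    int co = c.ch[l], Ho = c.Hs[l], Wo = c.Ws[l];
    int ci = (l == 0) ? 1 : c.ch[l - 1];
    int Hi = (l == 0) ? c.H0 : c.Hs[l - 1];
    int Wi = (l == 0) ? c.W0 : c.Ws[l - 1];
    NumericVector z = zl[l];
    NumericVector a = al[l];
    const double* W = params.begin() + c.woff[l];
    const double* gamma = W + (long)co * ci * 9 + co;
    double* gW = gparams.begin() + c.woff[l];
    double* gb = gW + (long)co * ci * 9;
    double* ggamma = gb + co;
    double* gbeta = ggamma + co;
    long m = (long)B * Ho * Wo;
    // ReLU + BN backward -> gz
    NumericVector gz((long)B * co * Ho * Wo);
    for (int o = 0; o < co; ++o) {
      double mu = bstat[c.soff[l] + o];
      double var = bstat[c.soff[l] + co + o];
      double inv = 1.0 / std::sqrt(var + eps);
      double sum_gy = 0, sum_gy_xh = 0;
      // first pass: ReLU gate, gamma/beta grads, stat sums
      for (int b2 = 0; b2 < B; ++b2) {
        const double* zp = z.begin() + ((long)b2 * co + o) * Ho * Wo;
        const double* ap = a.begin() + ((long)b2 * co + o) * Ho * Wo;
        double* gp = ga.begin();  // placeholder, not used here
        (void)gp;
        for (long q = 0; q < (long)Ho * Wo; ++q) {
          long li = ((long)b2 * co + o) * Ho * Wo + q;
          double gy = (ap[q] > 0) ? ga[li] : 0.0;
          double xh = (zp[q] - mu) * inv;
          ggamma[o] += gy * xh;
          gbeta[o] += gy;
          sum_gy += gy;
          sum_gy_xh += gy * xh;
          gz[li] = gy;  // stash gated gy
        }
      }
      double k1 = sum_gy / m, k2 = sum_gy_xh / m;
      for (int b2 = 0; b2 < B; ++b2) {
        const double* zp = z.begin() + ((long)b2 * co + o) * Ho * Wo;
        for (long q = 0; q < (long)Ho * Wo; ++q) {
          long li = ((long)b2 * co + o) * Ho * Wo + q;
          double gy = gz[li];
          double xh = (zp[q] - mu) * inv;
          if (train)
            gz[li] = gamma[o] * inv * (gy - k1 - xh * k2);
          else
            gz[li] = gamma[o] * inv * gy;
        }
      }
    }
    // conv backward -> gin, gW, gb
    const double* in = (l == 0) ? x.begin() : ((NumericVector)al[l - 1]).begin();
    bool want_gin = (l > 0) || need_ginput;
    NumericVector gin(want_gin ? (long)B * ci * Hi * Wi : 0);
    for (int bb = 0; bb < B; ++bb)
      for (int o = 0; o < co; ++o) {
        const double* gzp = gz.begin() + ((long)bb * co + o) * Ho * Wo;
        for (int wo = 0; wo < Wo; ++wo)
          for (int ho = 0; ho < Ho; ++ho) {
            double gv = gzp[ho + (long)Ho * wo];
            if (gv == 0.0) continue;
            gb[o] += gv;
            int hi0 = 2 * ho - 1, wi0 = 2 * wo - 1;
            for (int i = 0; i < ci; ++i) {
              const double* ip = in + ((long)bb * ci + i) * Hi * Wi;
              const double* wk = W + ((long)o * ci + i) * 9;
              double* gwk = gW + ((long)o * ci + i) * 9;
              double* gip = want_gin ? gin.begin() + ((long)bb * ci + i) * Hi * Wi
                                     : nullptr;
              for (int kh = 0; kh < 3; ++kh) {
                int hi = hi0 + kh;
                if (hi < 0 || hi >= Hi) continue;
                for (int kw = 0; kw < 3; ++kw) {
                  int wi = wi0 + kw;
                  if (wi < 0 || wi >= Wi) continue;
                  gwk[kh * 3 + kw] += gv * ip[hi + (long)Hi * wi];
                  if (want_gin) gip[hi + (long)Hi * wi] += gv * wk[kh * 3 + kw];
                }
              }
            }
          }
      }
    ga = gin;  // gradient w.r.t. this layer's input
  }
  return List::create(_["gparams"] = gparams, _["ginput"] = ga);
}

// Bilinear resize of a 2D matrix (used to bring projections to the fixed
// encoder input size).
// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(NumericMatrix src, int nh, int nw) {
  int h = src.nrow(), w = src.ncol();
  NumericMatrix out(nh, nw);
  for (int j = 0; j < nw; ++j) {
    double cx = (w == 1 || nw == 1) ? 0.0 : (double)j * (w - 1) / (nw - 1);
    int x0 = (int)cx; if (x0 > w - 2) x0 = w >= 2 ? w - 2 : 0;
    double fx = cx - x0;
    int x1 = w >= 2 ? x0 + 1 : x0;
    for (int i = 0; i < nh; ++i) {
      double cy = (h == 1 || nh == 1) ? 0.0 : (double)i * (h - 1) / (nh - 1);
      int y0 = (int)cy; if (y0 > h - 2) y0 = h >= 2 ? h - 2 : 0;
      double fy = cy - y0;
      int y1 = h >= 2 ? y0 + 1 : y0;
      out(i, j) = (1 - fy) * ((1 - fx) * src(y0, x0) + fx * src(y0, x1)) +
                  fy * ((1 - fx) * src(y1, x0) + fx * src(y1, x1));
    }
  }
  return out;
}

// Adjoint of cpp_resize_bilinear (gradient of the resized image back to the
// source grid).
// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear_adjoint(NumericMatrix gout, int h, int w) {
  int nh = gout.nrow(), nw = gout.ncol();
  NumericMatrix gsrc(h, w);
  for (int j = 0; j < nw; ++j) {
    double cx = (w == 1 || nw == 1) ? 0.0 : (double)j * (w - 1) / (nw - 1);
    int x0 = (int)cx; if (x0 > w - 2) x0 = w >= 2 ? w - 2 : 0;
    double fx = cx - x0;
    int x1 = w >= 2 ? x0 + 1 : x0;
    for (int i = 0; i < nh; ++i) {
      double cy = (h == 1 || nh == 1) ? 0.0 : (double)i * (h - 1) / (nh - 1);
      int y0 = (int)cy; if (y0 > h - 2) y0 = h >= 2 ? h - 2 : 0;
      double fy = cy - y0;
      int y1 = h >= 2 ? y0 + 1 : y0;
      double g = gout(i, j);
      gsrc(y0, x0) += (1 - fy) * (1 - fx) * g;
      gsrc(y0, x1) += (1 - fy) * fx * g;
      gsrc(y1, x0) += fy * (1 - fx) * g;
      gsrc(y1, x1) += fy * fx * g;
    }
  }
  return gsrc;
}
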