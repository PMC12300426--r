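// Dense tensor kernels for the segmentation network.
//
// Tensor layout convention (column-major R arrays): [H, W, C, B], so a single
// sample's channel plane is contiguous. Weights are [KH, KW, Cin, Cout].
// Convolutions are implemented as im2col + GEMM; the backward pass recomputes
// the patch matrix instead of caching it, trading ~30% FLOPs for memory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// reflect-101 index mapping: -1 -> 1, n -> n-2 (no edge duplication).
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

static void im2col_sample(const double* x, int H, int W, int C,
                          int KH, int KW, int OH, int OW,
                          int stride, int dil, int pad, int pad_mode,
                          arma::fmat& cols) {
  // cols: (KH*KW*C) x (OH*OW), row index k = kh + KH*(kw + KW*c)
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        int k = kh + KH * (kw + KW * c);
        float* col_row = cols.memptr() + k; // stride KH*KW*C between cols
        int nrow = cols.n_rows;
        for (int ow = 0; ow < OW; ++ow) {
          int iw = ow * stride - pad + kw * dil;
          for (int oh = 0; oh < OH; ++oh) {
            int ih = oh * stride - pad + kh * dil;
            int o = oh + OH * ow;
            double v;
            if (pad_mode == 1) {
              v = xc[reflect_idx(ih, H) + H * reflect_idx(iw, W)];
            } else {
              v = (ih >= 0 && ih < H && iw >= 0 && iw < W)
                    ? xc[ih + H * iw] : 0.0;
            }
            col_row[(size_t)o * nrow] = (float)v;
          }
        }
      }
    }
  }
}

static void col2im_sample(const arma::fmat& gcols, int H, int W, int C,
                          int KH, int KW, int OH, int OW,
                          int stride, int dil, int pad, int pad_mode,
                          double* gx) {
  for (int c = 0; c < C; ++c) {
    double* gxc = gx + (size_t)H * W * c;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        int k = kh + KH * (kw + KW * c);
        const float* col_row = gcols.memptr() + k;
        int nrow = gcols.n_rows;
        for (int ow = 0; ow < OW; ++ow) {
          int iw = ow * stride - pad + kw * dil;
          for (int oh = 0; oh < OH; ++oh) {
            int ih = oh * stride - pad + kh * dil;
            int o = oh + OH * ow;
            double g = (double)col_row[(size_t)o * nrow];
            if (g == 0.0) continue;
            if (pad_mode == 1) {
              gxc[reflect_idx(ih, H) + H * reflect_idx(iw, W)] += g;
            } else if (ih >= 0 && ih < H && iw >= 0 && iw < W) {
              gxc[ih + H * iw] += g;
            }
          }
        }
      }
    }
  }
}

static inline NumericVector make4(int a, int b, int c, int d) {
  NumericVector v(Dimension((size_t)a * b, (size_t)c, (size_t)d));
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline int out_size(int n, int k, int stride, int dil, int pad) {
  int eff = (k - 1) * dil + 1;
  return (n + 2 * pad - eff) / stride + 1;
}

typedef arma::fmat ColsCache;

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
List cpp_conv2d_fwd(NumericVector x, NumericVector w,
                    NumericVector bias, int stride, int dil,
                    int pad, int pad_mode, bool keep_cache) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int KH = wd[0], KW = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  int OH = out_size(H, KH, stride, dil, pad);
  int OW = out_size(W, KW, stride, dil, pad);
  if (OH < 1 || OW < 1) stop("conv2d: input smaller than receptive field");
  int K = KH * KW * C;
  size_t ohw = (size_t)OH * OW;
  bool one_by_one = (KH == 1 && KW == 1 && stride == 1 && pad == 0);

  NumericVector y = make4(OH, OW, Cout, B);
  arma::mat Wd(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::fmat Wm = arma::conv_to<arma::fmat>::from(Wd);
  bool has_b = bias.size() == Cout;
  Rcpp::XPtr<ColsCache> cache(new ColsCache(), true);

  arma::fmat Yall;
  if (one_by_one) {
    // channel matrix view of the whole batch in one GEMM
    arma::fmat Xf(H * W, C * B);
    const double* px = x.begin();
    float* pf = Xf.memptr();
    for (size_t i = 0; i < (size_t)H * W * C * B; ++i) pf[i] = (float)px[i];
    Yall.set_size(ohw, (size_t)Cout * B);
    for (int b = 0; b < B; ++b)
      Yall.cols((size_t)b * Cout, (size_t)(b + 1) * Cout - 1) =
          Xf.cols((size_t)b * C, (size_t)(b + 1) * C - 1) * Wm;
    double* yp = y.begin();
    const float* src = Yall.memptr();
    for (size_t j = 0; j < (size_t)Cout * B; ++j) {
      double bb = has_b ? bias[j % Cout] : 0.0;
      for (size_t o = 0; o < ohw; ++o)
        yp[o + ohw * j] = (double)src[o + ohw * j] + bb;
    }
    return List::create(_["y"] = y, _["cache"] = cache);
  }

  arma::fmat cols(K, ohw * B);
  for (int b = 0; b < B; ++b) {
    arma::fmat view(cols.colptr(ohw * b), K, ohw, false, true);
    im2col_sample(x.begin() + (size_t)H * W * C * b, H, W, C, KH, KW,
                  OH, OW, stride, dil, pad, pad_mode, view);
  }
  Yall = cols.t() * Wm;   // (OHW*B) x Cout, rows ordered (o, b)
  double* yp = y.begin();
  for (int b = 0; b < B; ++b)
    for (int co = 0; co < Cout; ++co) {
      double bb = has_b ? bias[co] : 0.0;
      const float* src = Yall.colptr(co) + ohw * b;
      double* dst = yp + ohw * (co + (size_t)Cout * b);
      for (size_t o = 0; o < ohw; ++o) dst[o] = (double)src[o] + bb;
    }
  if (keep_cache) *cache = std::move(cols);
  return List::create(_["y"] = y, _["cache"] = cache);
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int dil, int pad, int pad_mode,
                    bool need_gx, SEXP cache_sexp) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"),
                gd = gy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int KH = wd[0], KW = wd[1], Cout = wd[3];
  int OH = gd[0], OW = gd[1];
  int K = KH * KW * C;
  size_t ohw = (size_t)OH * OW;
  bool one_by_one = (KH == 1 && KW == 1 && stride == 1 && pad == 0);
  Rcpp::XPtr<ColsCache> cache(cache_sexp);

  NumericVector gx = make4(H, W, C, B);
  NumericVector gw = make4(KH, KW, C, Cout);
  NumericVector gb(Cout);
  arma::mat Wd(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::fmat Wm = arma::conv_to<arma::fmat>::from(Wd);
  arma::vec gbv(gb.begin(), Cout, false, true);

  // gather gy as float (OHW*B) x Cout with rows ordered (o, b)
  arma::fmat gY(ohw * B, Cout);
  for (int b = 0; b < B; ++b)
    for (int co = 0; co < Cout; ++co) {
      const double* src = gy.begin() + ohw * (co + (size_t)Cout * b);
      float* dst = gY.colptr(co) + ohw * b;
      double s = 0.0;
      for (size_t o = 0; o < ohw; ++o) { dst[o] = (float)src[o]; s += src[o]; }
      gbv[co] += s;
    }

  arma::fmat gWm;
  if (one_by_one) {
    arma::fmat Xf((size_t)H * W, (size_t)C * B);
    const double* px = x.begin();
    float* pf = Xf.memptr();
    for (size_t i = 0; i < (size_t)H * W * C * B; ++i) pf[i] = (float)px[i];
    gWm.zeros(K, Cout);
    for (int b = 0; b < B; ++b) {
      arma::fmat Xb(Xf.colptr((size_t)b * C), ohw, C, false, true);
      gWm += Xb.t() * gY.rows(ohw * b, ohw * (b + 1) - 1);
      if (need_gx) {
        arma::fmat gXb = gY.rows(ohw * b, ohw * (b + 1) - 1) * Wm.t();
        double* gp = gx.begin() + (size_t)H * W * C * b;
        const float* sp = gXb.memptr();
        for (size_t i = 0; i < (size_t)H * W * C; ++i) gp[i] = (double)sp[i];
      }
    }
  } else {
    bool use_cache = cache->n_cols == ohw * B && cache->n_rows == (size_t)K;
    arma::fmat cols_local;
    const arma::fmat* cp;
    if (use_cache) {
      cp = cache.get();
    } else {
      cols_local.set_size(K, ohw * B);
      for (int b = 0; b < B; ++b) {
        arma::fmat view(cols_local.colptr(ohw * b), K, ohw, false, true);
        im2col_sample(x.begin() + (size_t)H * W * C * b, H, W, C, KH, KW,
                      OH, OW, stride, dil, pad, pad_mode, view);
      }
      cp = &cols_local;
    }
    gWm = (*cp) * gY;
    if (need_gx) {
      arma::fmat gcols = Wm * gY.t();   // K x (OHW*B)
      for (int b = 0; b < B; ++b) {
        arma::fmat view(gcols.colptr(ohw * b), K, ohw, false, true);
        col2im_sample(view, H, W, C, KH, KW, OH, OW, stride, dil, pad,
                      pad_mode, gx.begin() + (size_t)H * W * C * b);
      }
    }
  }
  arma::mat gWout(gw.begin(), K, Cout, false, true);
  gWout = arma::conv_to<arma::mat>::from(gWm);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Adaptive average pooling (PyTorch binning: bin i covers
// [floor(i*H/OH), ceil((i+1)*H/OH)) ).
// [[Rcpp::export(name = ".cpp_adaptive_avgpool_fwd")]]
NumericVector cpp_adaptive_avgpool_fwd(NumericVector x, int OH, int OW) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  NumericVector y = make4(OH, OW, C, B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * b);
      double* yc = y.begin() + (size_t)OH * OW * (c + (size_t)C * b);
      for (int ow = 0; ow < OW; ++ow) {
        int w0 = (ow * W) / OW, w1 = ((ow + 1) * W + OW - 1) / OW;
        for (int oh = 0; oh < OH; ++oh) {
          int h0 = (oh * H) / OH, h1 = ((oh + 1) * H + OH - 1) / OH;
          double s = 0.0;
          for (int iw = w0; iw < w1; ++iw)
            for (int ih = h0; ih < h1; ++ih) s += xc[ih + H * iw];
          yc[oh + OH * ow] = s / ((h1 - h0) * (w1 - w0));
        }
      }
    }
  return y;
}

// [[Rcpp::export(name = ".cpp_adaptive_avgpool_bwd")]]
NumericVector cpp_adaptive_avgpool_bwd(NumericVector gy, int H, int W) {
  IntegerVector gd = gy.attr("dim");
  int OH = gd[0], OW = gd[1], C = gd[2], B = gd[3];
  NumericVector gx = make4(H, W, C, B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      double* gxc = gx.begin() + (size_t)H * W * (c + (size_t)C * b);
      const double* gyc =
          gy.begin() + (size_t)OH * OW * (c + (size_t)C * b);
      for (int ow = 0; ow < OW; ++ow) {
        int w0 = (ow * W) / OW, w1 = ((ow + 1) * W + OW - 1) / OW;
        for (int oh = 0; oh < OH; ++oh) {
          int h0 = (oh * H) / OH, h1 = ((oh + 1) * H + OH - 1) / OH;
          double g = gyc[oh + OH * ow] / ((h1 - h0) * (w1 - w0));
          for (int iw = w0; iw < w1; ++iw)
            for (int ih = h0; ih < h1; ++ih) gxc[ih + H * iw] += g;
        }
      }
    }
  return gx;
}

// Bilinear x2 upsampling, align_corners = FALSE convention.
// [[Rcpp::export(name = ".cpp_upsample2x_fwd")]]
NumericVector cpp_upsample2x_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int OH = 2 * H, OW = 2 * W;
  NumericVector y = make4(OH, OW, C, B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * b);
      double* yc = y.begin() + (size_t)OH * OW * (c + (size_t)C * b);
      for (int ow = 0; ow < OW; ++ow) {
        double sw = (ow + 0.5) / 2.0 - 0.5;
        int w0 = (int)std::floor(sw);
        double fw = sw - w0;
        int w0c = std::max(0, std::min(w0, W - 1));
        int w1c = std::max(0, std::min(w0 + 1, W - 1));
        for (int oh = 0; oh < OH; ++oh) {
          double sh = (oh + 0.5) / 2.0 - 0.5;
          int h0 = (int)std::floor(sh);
          double fh = sh - h0;
          int h0c = std::max(0, std::min(h0, H - 1));
          int h1c = std::max(0, std::min(h0 + 1, H - 1));
          yc[oh + OH * ow] =
              (1 - fh) * (1 - fw) * xc[h0c + H * w0c] +
              fh * (1 - fw) * xc[h1c + H * w0c] +
              (1 - fh) * fw * xc[h0c + H * w1c] +
              fh * fw * xc[h1c + H * w1c];
        }
      }
    }
  return y;
}

// [[Rcpp::export(name = ".cpp_upsample2x_bwd")]]
NumericVector cpp_upsample2x_bwd(NumericVector gy) {
  IntegerVector gd = gy.attr("dim");
  int OH = gd[0], OW = gd[1], C = gd[2], B = gd[3];
  int H = OH / 2, W = OW / 2;
  NumericVector gx = make4(H, W, C, B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      double* gxc = gx.begin() + (size_t)H * W * (c + (size_t)C * b);
      const double* gyc =
          gy.begin() + (size_t)OH * OW * (c + (size_t)C * b);
      for (int ow = 0; ow < OW; ++ow) {
        double sw = (ow + 0.5) / 2.0 - 0.5;
        int w0 = (int)std::floor(sw);
        double fw = sw - w0;
        int w0c = std::max(0, std::min(w0, W - 1));
        int w1c = std::max(0, std::min(w0 + 1, W - 1));
        for (int oh = 0; oh < OH; ++oh) {
          double sh = (oh + 0.5) / 2.0 - 0.5;
          int h0 = (int)std::floor(sh);
          double fh = sh - h0;
          int h0c = std::max(0, std::min(h0, H - 1));
          int h1c = std::max(0, std::min(h0 + 1, H - 1));
          double g = gyc[oh + OH * ow];
          gxc[h0c + H * w0c] += (1 - fh) * (1 - fw) * g;
          gxc[h1c + H * w0c] += fh * (1 - fw) * g;
          gxc[h0c + H * w1c] += (1 - fh) * fw * g;
          gxc[h1c + H * w1c] += fh * fw * g;
        }
      }
    }
  return gx;
}

// Row softmax over the second index of an [N, M, B] array: each (n, b)
// slice along M becomes a probability distribution.
// [[Rcpp::export(name = ".cpp_softmax3_fwd")]]
NumericVector cpp_softmax3_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int N = xd[0], M = xd[1], B = xd[2];
  NumericVector p(x.size());
  p.attr("dim") = xd;
  for (int b = 0; b < B; ++b) {
    const double* xb = x.begin() + (size_t)N * M * b;
    double* pb = p.begin() + (size_t)N * M * b;
    for (int n = 0; n < N; ++n) {
      double mx = -INFINITY;
      for (int m = 0; m < M; ++m) mx = std::max(mx, xb[n + (size_t)N * m]);
      double s = 0.0;
      for (int m = 0; m < M; ++m) {
        double e = std::exp(xb[n + (size_t)N * m] - mx);
        pb[n + (size_t)N * m] = e;
        s += e;
      }
      double inv = 1.0 / s;
      for (int m = 0; m < M; ++m) pb[n + (size_t)N * m] *= inv;
    }
  }
  return p;
}

// [[Rcpp::export(name = ".cpp_softmax3_bwd")]]
NumericVector cpp_softmax3_bwd(NumericVector p, NumericVector g) {
  IntegerVector pd = p.attr("dim");
  int N = pd[0], M = pd[1], B = pd[2];
  NumericVector gx(p.size());
  gx.attr("dim") = pd;
  for (int b = 0; b < B; ++b) {
    const double* pb = p.begin() + (size_t)N * M * b;
    const double* gb = g.begin() + (size_t)N * M * b;
    double* ob = gx.begin() + (size_t)N * M * b;
    for (int n = 0; n < N; ++n) {
      double dot = 0.0;
      for (int m = 0; m < M; ++m)
        dot += gb[n + (size_t)N * m] * pb[n + (size_t)N * m];
      for (int m = 0; m < M; ++m)
        ob[n + (size_t)N * m] =
            pb[n + (size_t)N * m] * (gb[n + (size_t)N * m] - dot);
    }
  }
  return gx;
}

// Per-channel statistics of an [H,W,C,B] tensor: returns C-vectors of the
// mean and mean-of-squares over (H, W, B).
// [[Rcpp::export(name = ".cpp_chan_stats")]]
List cpp_chan_stats(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  size_t hw = (size_t)H * W;
  NumericVector mu(C), ex2(C);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + hw * (c + (size_t)C * b);
      double s = 0.0, s2 = 0.0;
      for (size_t i = 0; i < hw; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      mu[c] += s; ex2[c] += s2;
    }
  double n = (double)hw * B;
  for (int c = 0; c < C; ++c) { mu[c] /= n; ex2[c] /= n; }
  return List::create(_["mean"] = mu, _["ex2"] = ex2);
}

// y = x * a[c] + b[c] channelwise
// [[Rcpp::export(name = ".cpp_chan_affine")]]
NumericVector cpp_chan_affine(NumericVector x, NumericVector a,
                              NumericVector bb) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  size_t hw = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + hw * (c + (size_t)C * b);
      double* q = y.begin() + hw * (c + (size_t)C * b);
      double av = a[c], bv = bb[c];
      for (size_t i = 0; i < hw; ++i) q[i] = p[i] * av + bv;
    }
  return y;
}

// y = g * a[c] + xh * b[c] channelwise (batch-norm input gradient)
// [[Rcpp::export(name = ".cpp_chan_axpby")]]
NumericVector cpp_chan_axpby(NumericVector g, NumericVector xh,
                             NumericVector a, NumericVector bb,
                             NumericVector cc) {
  IntegerVector xd = g.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  size_t hw = (size_t)H * W;
  NumericVector y(g.size());
  y.attr("dim") = xd;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* pg = g.begin() + hw * (c + (size_t)C * b);
      const double* px = xh.begin() + hw * (c + (size_t)C * b);
      double* q = y.begin() + hw * (c + (size_t)C * b);
      double av = a[c], bv = bb[c], cv = cc[c];
      for (size_t i = 0; i < hw; ++i) q[i] = pg[i] * av + px[i] * bv + cv;
    }
  return y;
}

// per-channel sums of g and g*xh
// [[Rcpp::export(name = ".cpp_chan_dots")]]
List cpp_chan_dots(NumericVector g, NumericVector xh) {
  IntegerVector xd = g.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  size_t hw = (size_t)H * W;
  NumericVector sg(C), sgx(C);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* pg = g.begin() + hw * (c + (size_t)C * b);
      const double* px = xh.begin() + hw * (c + (size_t)C * b);
      double s = 0.0, s2 = 0.0;
      for (size_t i = 0; i < hw; ++i) { s += pg[i]; s2 += pg[i] * px[i]; }
      sg[c] += s; sgx[c] += s2;
    }
  return List::create(_["sum_g"] = sg, _["sum_gx"] = sgx);
}

// [[Rcpp::export(name = ".cpp_relu_fwd")]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* p = x.begin(); double* q = y.begin();
  for (size_t i = 0; i < (size_t)x.size(); ++i)
    q[i] = p[i] > 0 ? p[i] : 0.0;
  return y;
}

// [[Rcpp::export(name = ".cpp_relu_bwd")]]
NumericVector cpp_relu_bwd(NumericVector y, NumericVector g) {
  NumericVector gx(g.size());
  gx.attr("dim") = g.attr("dim");
  const double* py = y.begin(); const double* pg = g.begin();
  double* q = gx.begin();
  for (size_t i = 0; i < (size_t)g.size(); ++i)
    q[i] = py[i] > 0 ? pg[i] : 0.0;
  return gx;
}

// y[,,,b] = x[,,,b] * w[b]
// [[Rcpp::export(name = ".cpp_scale_sample_fwd")]]
NumericVector cpp_scale_sample_fwd(NumericVector x, NumericVector w) {
  IntegerVector xd = x.attr("dim");
  size_t n = (size_t)xd[0] * xd[1] * xd[2];
  int B = xd[3];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  for (int b = 0; b < B; ++b) {
    const double* p = x.begin() + n * b;
    double* q = y.begin() + n * b;
    double wv = w[b];
    for (size_t i = 0; i < n; ++i) q[i] = p[i] * wv;
  }
  return y;
}

// gx[,,,b] = g[,,,b] * w[b]; gw[b] = sum(g[,,,b] * x[,,,b])
// [[Rcpp::export(name = ".cpp_scale_sample_bwd")]]
List cpp_scale_sample_bwd(NumericVector x, NumericVector w,
                          NumericVector g) {
  IntegerVector xd = x.attr("dim");
  size_t n = (size_t)xd[0] * xd[1] * xd[2];
  int B = xd[3];
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(B);
  for (int b = 0; b < B; ++b) {
    const double* px = x.begin() + n * b;
    const double* pg = g.begin() + n * b;
    double* q = gx.begin() + n * b;
    double wv = w[b], s = 0.0;
    for (size_t i = 0; i < n; ++i) {
      q[i] = pg[i] * wv;
      s += pg[i] * px[i];
    }
    gw[b] = s;
  }
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// Batched per-sample matmul on [.,.,B] arrays with transpose flags,
// computed in float. Returns C = op(A) * op(B) per sample.
static arma::fmat to_f(const NumericVector& x, size_t n) {
  arma::fmat f(1, n);
  const double* p = x.begin();
  float* q = f.memptr();
  for (size_t i = 0; i < n; ++i) q[i] = (float)p[i];
  return f;
}

// [[Rcpp::export(name = ".cpp_bmm_fwd")]]
NumericVector cpp_bmm_fwd(NumericVector a, NumericVector b,
                          bool ta, bool tb) {
  IntegerVector ad = a.attr("dim"), bd = b.attr("dim");
  int ar = ad[0], ac = ad[1], br = bd[0], bc = bd[1], B = ad[2];
  int M = ta ? ac : ar, K = ta ? ar : ac, N = tb ? br : bc;
  if ((tb ? bc : br) != K) stop("bmm: inner dimension mismatch");
  arma::fmat af = to_f(a, (size_t)ar * ac * B);
  arma::fmat bf = to_f(b, (size_t)br * bc * B);
  NumericVector y((size_t)M * N * B);
  y.attr("dim") = IntegerVector::create(M, N, B);
  arma::fmat Cb(M, N);
  for (int i = 0; i < B; ++i) {
    arma::fmat Ab(af.memptr() + (size_t)ar * ac * i, ar, ac, false, true);
    arma::fmat Bb(bf.memptr() + (size_t)br * bc * i, br, bc, false, true);
    if (!ta && !tb) Cb = Ab * Bb;
    else if (!ta && tb) Cb = Ab * Bb.t();
    else if (ta && !tb) Cb = Ab.t() * Bb;
    else Cb = Ab.t() * Bb.t();
    double* yp = y.begin() + (size_t)M * N * i;
    const float* cp = Cb.memptr();
    for (size_t j = 0; j < (size_t)M * N; ++j) yp[j] = (double)cp[j];
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_bmm_bwd")]]
List cpp_bmm_bwd(NumericVector a, NumericVector b, NumericVector g,
                 bool ta, bool tb) {
  IntegerVector ad = a.attr("dim"), bd = b.attr("dim"),
                gd = g.attr("dim");
  int ar = ad[0], ac = ad[1], br = bd[0], bc = bd[1], B = ad[2];
  int M = gd[0], N = gd[1];
  arma::fmat af = to_f(a, (size_t)ar * ac * B);
  arma::fmat bf = to_f(b, (size_t)br * bc * B);
  arma::fmat gf = to_f(g, (size_t)M * N * B);
  NumericVector ga((size_t)ar * ac * B), gb((size_t)br * bc * B);
  ga.attr("dim") = ad; gb.attr("dim") = bd;
  arma::fmat gA(ar, ac), gB(br, bc);
  for (int i = 0; i < B; ++i) {
    arma::fmat Ab(af.memptr() + (size_t)ar * ac * i, ar, ac, false, true);
    arma::fmat Bb(bf.memptr() + (size_t)br * bc * i, br, bc, false, true);
    arma::fmat Gb(gf.memptr() + (size_t)M * N * i, M, N, false, true);
    if (!ta && !tb) { gA = Gb * Bb.t(); gB = Ab.t() * Gb; }
    else if (!ta && tb) { gA = Gb * Bb; gB = Gb.t() * Ab; }
    else if (ta && !tb) { gA = Bb * Gb.t(); gB = Ab * Gb; }
    else { gA = Bb.t() * Gb.t(); gB = Gb.t() * Ab.t(); }
    double* gap = ga.begin() + (size_t)ar * ac * i;
    const float* p1 = gA.memptr();
    for (size_t j = 0; j < (size_t)ar * ac; ++j) gap[j] = (double)p1[j];
    double* gbp = gb.begin() + (size_t)br * bc * i;
    const float* p2 = gB.memptr();
    for (size_t j = 0; j < (size_t)br * bc; ++j) gbp[j] = (double)p2[j];
  }
  return List::create(_["ga"] = ga, _["gb"] = gb);
}

// Double-precision 3x3 stencil convolution with reflect-101 padding on
// [H,W,1,B] tensors (used by the boundary losses, where gradient checks
// demand full double accuracy). The kernel is a fixed 3x3 matrix.
// [[Rcpp::export(name = ".cpp_stencil3_fwd")]]
NumericVector cpp_stencil3_fwd(NumericVector x, NumericMatrix k) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  for (int cb = 0; cb < C * B; ++cb) {
    const double* xc = x.begin() + (size_t)H * W * cb;
    double* yc = y.begin() + (size_t)H * W * cb;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        double acc = 0.0;
        for (int kw = 0; kw < 3; ++kw) {
          int iw = reflect_idx(w + kw - 1, W);
          for (int kh = 0; kh < 3; ++kh) {
            int ih = reflect_idx(h + kh - 1, H);
            acc += k(kh, kw) * xc[ih + H * iw];
          }
        }
        yc[h + H * w] = acc;
      }
  }
  return y;
}

// adjoint of the reflect-padded stencil: scatter-add g*k onto the inputs
// [[Rcpp::export(name = ".cpp_stencil3_bwd")]]
NumericVector cpp_stencil3_bwd(NumericVector g, NumericMatrix k) {
  IntegerVector gd = g.attr("dim");
  int H = gd[0], W = gd[1], C = gd[2], B = gd[3];
  NumericVector gx(g.size());
  gx.attr("dim") = gd;
  for (int cb = 0; cb < C * B; ++cb) {
    const double* gc = g.begin() + (size_t)H * W * cb;
    double* xc = gx.begin() + (size_t)H * W * cb;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        double gv = gc[h + H * w];
        if (gv == 0.0) continue;
        for (int kw = 0; kw < 3; ++kw) {
          int iw = reflect_idx(w + kw - 1, W);
          for (int kh = 0; kh < 3; ++kh) {
            int ih = reflect_idx(h + kh - 1, H);
            xc[ih + H * iw] += gv * k(kh, kw);
          }
        }
      }
  }
  return gx;
}
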