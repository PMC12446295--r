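#include <Rcpp.h>
using namespace Rcpp;

// Tensor layout throughout: column-major array dim c(C, H, W, N),
// i.e. flat index c + C*(h + H*(w + W*n)).
//
// im2col rows are ordered r = c + C*(ki + KH*kj) so that a weight array
// dim c(Cout, Cin, KH, KW) flattened to a Cout x (Cin*KH*KW) matrix lines
// up without any permutation. Columns are ordered col = oh + OH*(ow + OW*n)
// so the GEMM result reshapes directly to c(Cout, OH, OW, N).

// [[Rcpp::export(name = ".im2col_cpp")]]
NumericMatrix im2col_cpp(NumericVector x, int C, int H, int W, int N,
                         int KH, int KW, int stride, int pad) {
  const int OH = (H + 2 * pad - KH) / stride + 1;
  const int OW = (W + 2 * pad - KW) / stride + 1;
  NumericMatrix cols(C * KH * KW, OH * OW * N);
  const double *px = x.begin();
  double *pc = cols.begin();
  const int R = C * KH * KW;
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        const int col = oh + OH * (ow + OW * n);
        double *dst = pc + (R_xlen_t)col * R;
        for (int kj = 0; kj < KW; ++kj) {
          const int w = ow * stride - pad + kj;
          for (int ki = 0; ki < KH; ++ki) {
            const int h = oh * stride - pad + ki;
            double *d = dst + C * (ki + KH * kj);
            if (h >= 0 && h < H && w >= 0 && w < W) {
              const double *s = px + (R_xlen_t)C * (h + (R_xlen_t)H * (w + (R_xlen_t)W * n));
              for (int c = 0; c < C; ++c) d[c] = s[c];
            } else {
              for (int c = 0; c < C; ++c) d[c] = 0.0;
            }
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col: scatter-add columns back into the input tensor.
// [[Rcpp::export(name = ".col2im_cpp")]]
NumericVector col2im_cpp(NumericMatrix cols, int C, int H, int W, int N,
                         int KH, int KW, int stride, int pad) {
  const int OH = (H + 2 * pad - KH) / stride + 1;
  const int OW = (W + 2 * pad - KW) / stride + 1;
  NumericVector x((R_xlen_t)C * H * W * N);
  double *px = x.begin();
  const double *pc = cols.begin();
  const int R = C * KH * KW;
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        const int col = oh + OH * (ow + OW * n);
        const double *src = pc + (R_xlen_t)col * R;
        for (int kj = 0; kj < KW; ++kj) {
          const int w = ow * stride - pad + kj;
          if (w < 0 || w >= W) continue;
          for (int ki = 0; ki < KH; ++ki) {
            const int h = oh * stride - pad + ki;
            if (h < 0 || h >= H) continue;
            const double *s = src + C * (ki + KH * kj);
            double *d = px + (R_xlen_t)C * (h + (R_xlen_t)H * (w + (R_xlen_t)W * n));
            for (int c = 0; c < C; ++c) d[c] += s[c];
          }
        }
      }
    }
  }
  return x;
}

// Depthwise KxK convolution, weight layout c(C, K, K).
// [[Rcpp::export(name = ".dwconv_fwd_cpp")]]
NumericVector dwconv_fwd_cpp(NumericVector x, NumericVector w,
                             int C, int H, int W, int N,
                             int K, int stride, int pad) {
  const int OH = (H + 2 * pad - K) / stride + 1;
  const int OW = (W + 2 * pad - K) / stride + 1;
  NumericVector y((R_xlen_t)C * OH * OW * N);
  const double *px = x.begin(), *pw = w.begin();
  double *py = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        double *out = py + (R_xlen_t)C * (oh + (R_xlen_t)OH * (ow + (R_xlen_t)OW * n));
        for (int kj = 0; kj < K; ++kj) {
          const int wi = ow * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < K; ++ki) {
            const int hi = oh * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            const double *in = px + (R_xlen_t)C * (hi + (R_xlen_t)H * (wi + (R_xlen_t)W * n));
            const double *wk = pw + C * (ki + K * kj);
            for (int c = 0; c < C; ++c) out[c] += in[c] * wk[c];
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".dwconv_bwd_x_cpp")]]
NumericVector dwconv_bwd_x_cpp(NumericVector dy, NumericVector w,
                               int C, int H, int W, int N,
                               int K, int stride, int pad) {
  const int OH = (H + 2 * pad - K) / stride + 1;
  const int OW = (W + 2 * pad - K) / stride + 1;
  NumericVector dx((R_xlen_t)C * H * W * N);
  const double *pdy = dy.begin(), *pw = w.begin();
  double *pdx = dx.begin();
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        const double *g = pdy + (R_xlen_t)C * (oh + (R_xlen_t)OH * (ow + (R_xlen_t)OW * n));
        for (int kj = 0; kj < K; ++kj) {
          const int wi = ow * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < K; ++ki) {
            const int hi = oh * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            double *d = pdx + (R_xlen_t)C * (hi + (R_xlen_t)H * (wi + (R_xlen_t)W * n));
            const double *wk = pw + C * (ki + K * kj);
            for (int c = 0; c < C; ++c) d[c] += g[c] * wk[c];
          }
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export(name = ".dwconv_bwd_w_cpp")]]
NumericVector dwconv_bwd_w_cpp(NumericVector dy, NumericVector x,
                               int C, int H, int W, int N,
                               int K, int stride, int pad) {
  const int OH = (H + 2 * pad - K) / stride + 1;
  const int OW = (W + 2 * pad - K) / stride + 1;
  NumericVector dw((R_xlen_t)C * K * K);
  const double *pdy = dy.begin(), *px = x.begin();
  double *pdw = dw.begin();
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        const double *g = pdy + (R_xlen_t)C * (oh + (R_xlen_t)OH * (ow + (R_xlen_t)OW * n));
        for (int kj = 0; kj < K; ++kj) {
          const int wi = ow * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < K; ++ki) {
            const int hi = oh * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            const double *in = px + (R_xlen_t)C * (hi + (R_xlen_t)H * (wi + (R_xlen_t)W * n));
            double *d = pdw + C * (ki + K * kj);
            for (int c = 0; c < C; ++c) d[c] += g[c] * in[c];
          }
        }
      }
    }
  }
  return dw;
}

// Per-channel mean and (biased) variance over (H, W, N) in one pass.
// [[Rcpp::export(name = ".chan_stats_cpp")]]
List chan_stats_cpp(NumericVector x, int C) {
  const R_xlen_t m = x.size() / C;
  NumericVector mu(C), var(C);
  const double *px = x.begin();
  for (R_xlen_t j = 0; j < m; ++j) {
    const double *col = px + (R_xlen_t)C * j;
    for (int c = 0; c < C; ++c) {
      mu[c] += col[c];
      var[c] += col[c] * col[c];
    }
  }
  for (int c = 0; c < C; ++c) {
    mu[c] /= m;
    var[c] = var[c] / m - mu[c] * mu[c];
    if (var[c] < 0) var[c] = 0;
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// y = (x - mu) * ivar * gamma + beta, channel-recycled; also returns xhat.
// [[Rcpp::export(name = ".bn_apply_cpp")]]
List bn_apply_cpp(NumericVector x, NumericVector mu, NumericVector ivar,
                  NumericVector gamma, NumericVector beta) {
  const int C = mu.size();
  const R_xlen_t m = x.size() / C;
  NumericVector y(x.size()), xhat(x.size());
  const double *px = x.begin();
  double *py = y.begin(), *ph = xhat.begin();
  for (R_xlen_t j = 0; j < m; ++j) {
    const R_xlen_t off = (R_xlen_t)C * j;
    for (int c = 0; c < C; ++c) {
      const double h = (px[off + c] - mu[c]) * ivar[c];
      ph[off + c] = h;
      py[off + c] = h * gamma[c] + beta[c];
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// Training-mode BN backward in one pass:
//   dx = ivar * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)),
// with dxhat = dy * gamma; also emits dgamma/dbeta.
// [[Rcpp::export(name = ".bn_bwd_cpp")]]
List bn_bwd_cpp(NumericVector dy, NumericVector xhat, NumericVector ivar,
                NumericVector gamma, bool train) {
  const int C = ivar.size();
  const R_xlen_t m = dy.size() / C;
  NumericVector dgamma(C), dbeta(C), s1(C), s2(C), dx(dy.size());
  const double *pdy = dy.begin(), *ph = xhat.begin();
  double *pdx = dx.begin();
  for (R_xlen_t j = 0; j < m; ++j) {
    const R_xlen_t off = (R_xlen_t)C * j;
    for (int c = 0; c < C; ++c) {
      const double g = pdy[off + c];
      dbeta[c] += g;
      dgamma[c] += g * ph[off + c];
      const double dxh = g * gamma[c];
      s1[c] += dxh;
      s2[c] += dxh * ph[off + c];
    }
  }
  if (train) {
    for (int c = 0; c < C; ++c) { s1[c] /= m; s2[c] /= m; }
    for (R_xlen_t j = 0; j < m; ++j) {
      const R_xlen_t off = (R_xlen_t)C * j;
      for (int c = 0; c < C; ++c) {
        pdx[off + c] = ivar[c] *
          (pdy[off + c] * gamma[c] - s1[c] - ph[off + c] * s2[c]);
      }
    }
  } else {
    for (R_xlen_t j = 0; j < m; ++j) {
      const R_xlen_t off = (R_xlen_t)C * j;
      for (int c = 0; c < C; ++c) {
        pdx[off + c] = pdy[off + c] * gamma[c] * ivar[c];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Direct full-convolution backward w.r.t. the input:
// dx[c,h,w,n] = sum_{co,ki,kj} dy[co,oh,ow,n] * W[co,c,ki,kj].
// [[Rcpp::export(name = ".conv_bwd_x_cpp")]]
NumericVector conv_bwd_x_cpp(NumericVector dy, NumericVector w,
                             int Cin, int H, int W, int N,
                             int Cout, int KH, int KW, int stride, int pad) {
  const int OH = (H + 2 * pad - KH) / stride + 1;
  const int OW = (W + 2 * pad - KW) / stride + 1;
  NumericVector dx((R_xlen_t)Cin * H * W * N);
  const double *pdy = dy.begin(), *pw = w.begin();
  double *pdx = dx.begin();
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        const double *g = pdy +
          (R_xlen_t)Cout * (oh + (R_xlen_t)OH * (ow + (R_xlen_t)OW * n));
        for (int kj = 0; kj < KW; ++kj) {
          const int wi = ow * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < KH; ++ki) {
            const int hi = oh * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            double *d = pdx +
              (R_xlen_t)Cin * (hi + (R_xlen_t)H * (wi + (R_xlen_t)W * n));
            const double *wk = pw + (R_xlen_t)Cout * Cin * (ki + KH * kj);
            for (int c = 0; c < Cin; ++c) {
              const double *wc = wk + (R_xlen_t)Cout * c;
              double acc = 0.0;
              for (int co = 0; co < Cout; ++co) acc += g[co] * wc[co];
              d[c] += acc;
            }
          }
        }
      }
    }
  }
  return dx;
}

// Direct full-convolution backward w.r.t. the weights.
// [[Rcpp::export(name = ".conv_bwd_w_cpp")]]
NumericVector conv_bwd_w_cpp(NumericVector dy, NumericVector x,
                             int Cin, int H, int W, int N,
                             int Cout, int KH, int KW, int stride, int pad) {
  const int OH = (H + 2 * pad - KH) / stride + 1;
  const int OW = (W + 2 * pad - KW) / stride + 1;
  NumericVector dw((R_xlen_t)Cout * Cin * KH * KW);
  const double *pdy = dy.begin(), *px = x.begin();
  double *pdw = dw.begin();
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        const double *g = pdy +
          (R_xlen_t)Cout * (oh + (R_xlen_t)OH * (ow + (R_xlen_t)OW * n));
        for (int kj = 0; kj < KW; ++kj) {
          const int wi = ow * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < KH; ++ki) {
            const int hi = oh * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            const double *in = px +
              (R_xlen_t)Cin * (hi + (R_xlen_t)H * (wi + (R_xlen_t)W * n));
            double *d = pdw + (R_xlen_t)Cout * Cin * (ki + KH * kj);
            for (int c = 0; c < Cin; ++c) {
              double *dc = d + (R_xlen_t)Cout * c;
              const double xv = in[c];
              for (int co = 0; co < Cout; ++co) dc[co] += g[co] * xv;
            }
          }
        }
      }
    }
  }
  return dw;
}
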