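// 3D convolution kernels for the small EfficientNet-style CNN.
// Layout convention: volumes are R arrays with dim = c(D, H, W, C)
// (column-major, channel slowest); weights dim = c(kd, kh, kw, Cin/groups, Cout).
#include <Rcpp.h>
using namespace Rcpp;

static inline int out_len(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export(name = ".conv3d_forward")]]
NumericVector conv3d_forward(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             NumericVector bias,
                             int stride, int pad, int groups) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], Cin = xdim[3];
  const int kd = wdim[0], kh = wdim[1], kw = wdim[2];
  const int cig = wdim[3], Cout = wdim[4];
  if (Cin / groups != cig) stop("channel/group mismatch");
  const int cog = Cout / groups;
  const int Do = out_len(D, kd, stride, pad);
  const int Ho = out_len(H, kh, stride, pad);
  const int Wo = out_len(W, kw, stride, pad);
  NumericVector y(Do * Ho * Wo * Cout);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* yp = y.begin();

  for (int co = 0; co < Cout; ++co) {
    const int g = co / cog;
    const double b = bias[co];
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        for (int od = 0; od < Do; ++od) {
          double acc = b;
          for (int ci = 0; ci < cig; ++ci) {
            const int cin = g * cig + ci;
            const double* xc = xp + (size_t)cin * D * H * W;
            for (int c = 0; c < kw; ++c) {
              const int iw = ow * stride - pad + c;
              if (iw < 0 || iw >= W) continue;
              for (int bkh = 0; bkh < kh; ++bkh) {
                const int ih = oh * stride - pad + bkh;
                if (ih < 0 || ih >= H) continue;
                for (int a = 0; a < kd; ++a) {
                  const int id = od * stride - pad + a;
                  if (id < 0 || id >= D) continue;
                  acc += xc[id + (size_t)D * (ih + (size_t)H * iw)] *
                         wp[a + kd * (bkh + kh * (c + kw * (ci + (size_t)cig * co)))];
                }
              }
            }
          }
          yp[od + (size_t)Do * (oh + (size_t)Ho * (ow + (size_t)Wo * co))] = acc;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, Cout);
  return y;
}

// Gradient w.r.t. input: scatter dy back through the kernel.
// [[Rcpp::export(name = ".conv3d_backward_input")]]
NumericVector conv3d_backward_input(NumericVector dy, IntegerVector xdim,
                                    NumericVector w, IntegerVector wdim,
                                    int stride, int pad, int groups) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], Cin = xdim[3];
  const int kd = wdim[0], kh = wdim[1], kw = wdim[2];
  const int cig = wdim[3], Cout = wdim[4];
  const int cog = Cout / groups;
  const int Do = out_len(D, kd, stride, pad);
  const int Ho = out_len(H, kh, stride, pad);
  const int Wo = out_len(W, kw, stride, pad);
  NumericVector dx((size_t)D * H * W * Cin);
  const double* dyp = dy.begin();
  const double* wp = w.begin();
  double* dxp = dx.begin();

  for (int co = 0; co < Cout; ++co) {
    const int g = co / cog;
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        for (int od = 0; od < Do; ++od) {
          const double gout =
            dyp[od + (size_t)Do * (oh + (size_t)Ho * (ow + (size_t)Wo * co))];
          if (gout == 0.0) continue;
          for (int ci = 0; ci < cig; ++ci) {
            const int cin = g * cig + ci;
            double* xc = dxp + (size_t)cin * D * H * W;
            for (int c = 0; c < kw; ++c) {
              const int iw = ow * stride - pad + c;
              if (iw < 0 || iw >= W) continue;
              for (int bkh = 0; bkh < kh; ++bkh) {
                const int ih = oh * stride - pad + bkh;
                if (ih < 0 || ih >= H) continue;
                for (int a = 0; a < kd; ++a) {
                  const int id = od * stride - pad + a;
                  if (id < 0 || id >= D) continue;
                  xc[id + (size_t)D * (ih + (size_t)H * iw)] += gout *
                    wp[a + kd * (bkh + kh * (c + kw * (ci + (size_t)cig * co)))];
                }
              }
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = xdim;
  return dx;
}

// Gradients w.r.t. weights and bias; returns list(dw, db).
// [[Rcpp::export(name = ".conv3d_backward_weight")]]
List conv3d_backward_weight(NumericVector x, IntegerVector xdim,
                            NumericVector dy, IntegerVector wdim,
                            int stride, int pad, int groups) {
  const int D = xdim[0], H = xdim[1], W = xdim[2];
  const int kd = wdim[0], kh = wdim[1], kw = wdim[2];
  const int cig = wdim[3], Cout = wdim[4];
  const int cog = Cout / groups;
  const int Do = out_len(D, kd, stride, pad);
  const int Ho = out_len(H, kh, stride, pad);
  const int Wo = out_len(W, kw, stride, pad);
  NumericVector dw((size_t)kd * kh * kw * cig * Cout);
  NumericVector db(Cout);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  double* dwp = dw.begin();

  for (int co = 0; co < Cout; ++co) {
    const int g = co / cog;
    double bacc = 0.0;
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        for (int od = 0; od < Do; ++od) {
          const double gout =
            dyp[od + (size_t)Do * (oh + (size_t)Ho * (ow + (size_t)Wo * co))];
          bacc += gout;
          if (gout == 0.0) continue;
          for (int ci = 0; ci < cig; ++ci) {
            const int cin = g * cig + ci;
            const double* xc = xp + (size_t)cin * D * H * W;
            for (int c = 0; c < kw; ++c) {
              const int iw = ow * stride - pad + c;
              if (iw < 0 || iw >= W) continue;
              for (int bkh = 0; bkh < kh; ++bkh) {
                const int ih = oh * stride - pad + bkh;
                if (ih < 0 || ih >= H) continue;
                for (int a = 0; a < kd; ++a) {
                  const int id = od * stride - pad + a;
                  if (id < 0 || id >= D) continue;
                  dwp[a + kd * (bkh + kh * (c + kw * (ci + (size_t)cig * co)))] +=
                    gout * xc[id + (size_t)D * (ih + (size_t)H * iw)];
                }
              }
            }
          }
        }
      }
    }
    db[co] = bacc;
  }
  dw.attr("dim") = wdim;
  return List::create(_["dw"] = dw, _["db"] = db);
}
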