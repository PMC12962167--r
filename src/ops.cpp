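// Low-level spatiotemporal tensor primitives used by the HBP network.
//
// Layout conventions (column-major R arrays):
//   clip / feature tensors:  dim = (C, T, H, W, B)   channel fastest
//   convolution weights:     dim = (Co, Ci, kT, kH, kW)
// Convolutions are evaluated as chunked im2col + GEMM; chunking over output
// (or input, for transposed convolutions) positions bounds the size of the
// unrolled column matrix so full-resolution clips fit comfortably in memory.

#include <RcppArmadillo.h>
using namespace Rcpp;

// maximum number of doubles in one unrolled column-matrix chunk (~128 MB)
static const long long COL_BUDGET = 1LL << 24;

struct Dims {
  int C, T, H, W, B;
};

static Dims get_dims(const IntegerVector &d) {
  Dims out;
  out.C = d[0]; out.T = d[1]; out.H = d[2]; out.W = d[3];
  out.B = (d.size() > 4) ? d[4] : 1;
  return out;
}

static inline long long idx4(int c, int t, int h, int w, const Dims &d) {
  return c + (long long)d.C * (t + (long long)d.T * (h + (long long)d.H * w));
}

// Gather one im2col chunk: columns are output positions [p0, p1), rows are
// (ci, kt, kh, kw) with ci fastest, matching the weight-matrix column order.
static void im2col_chunk(const double *x, const Dims &xd,
                         int To, int Ho, int Wo,
                         int kT, int kH, int kW,
                         int st, int sh, int sw,
                         int pt, int ph, int pw,
                         long long p0, long long p1, arma::mat &col) {
  const int Ci = xd.C;
  col.zeros();
  for (long long p = p0; p < p1; ++p) {
    long long q = p;
    const int to = (int)(q % To); q /= To;
    const int ho = (int)(q % Ho); q /= Ho;
    const int wo = (int)q;
    const int t0 = to * st - pt, h0 = ho * sh - ph, w0 = wo * sw - pw;
    double *dst = col.colptr(p - p0);
    for (int kw = 0; kw < kW; ++kw) {
      const int iw = w0 + kw;
      for (int kh = 0; kh < kH; ++kh) {
        const int ih = h0 + kh;
        for (int kt = 0; kt < kT; ++kt) {
          const int it = t0 + kt;
          double *d = dst + (long long)Ci * (kt + (long long)kT * (kh + (long long)kH * kw));
          if (it >= 0 && it < xd.T && ih >= 0 && ih < xd.H && iw >= 0 && iw < xd.W) {
            const double *s = x + idx4(0, it, ih, iw, xd);
            std::copy(s, s + Ci, d);
          }
        }
      }
    }
  }
}

// Scatter-accumulate one column chunk back into the input gradient (col2im).
static void col2im_chunk(const arma::mat &col, double *dx, const Dims &xd,
                         int To, int Ho, int Wo,
                         int kT, int kH, int kW,
                         int st, int sh, int sw,
                         int pt, int ph, int pw,
                         long long p0, long long p1) {
  const int Ci = xd.C;
  for (long long p = p0; p < p1; ++p) {
    long long q = p;
    const int to = (int)(q % To); q /= To;
    const int ho = (int)(q % Ho); q /= Ho;
    const int wo = (int)q;
    const int t0 = to * st - pt, h0 = ho * sh - ph, w0 = wo * sw - pw;
    const double *src = col.colptr(p - p0);
    for (int kw = 0; kw < kW; ++kw) {
      const int iw = w0 + kw;
      if (iw < 0 || iw >= xd.W) continue;
      for (int kh = 0; kh < kH; ++kh) {
        const int ih = h0 + kh;
        if (ih < 0 || ih >= xd.H) continue;
        for (int kt = 0; kt < kT; ++kt) {
          const int it = t0 + kt;
          if (it < 0 || it >= xd.T) continue;
          const double *s = src + (long long)Ci * (kt + (long long)kT * (kh + (long long)kH * kw));
          double *d = dx + idx4(0, it, ih, iw, xd);
          for (int ci = 0; ci < Ci; ++ci) d[ci] += s[ci];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             NumericVector bias,
                             IntegerVector stride, IntegerVector pad) {
  Dims xd = get_dims(xdim);
  const int Co = wdim[0], Ci = wdim[1], kT = wdim[2], kH = wdim[3], kW = wdim[4];
  if (Ci != xd.C) stop("conv3d: input has %d channels, weights expect %d", xd.C, Ci);
  const int st = stride[0], sh = stride[1], sw = stride[2];
  const int pt = pad[0], ph = pad[1], pw = pad[2];
  const int To = (xd.T + 2 * pt - kT) / st + 1;
  const int Ho = (xd.H + 2 * ph - kH) / sh + 1;
  const int Wo = (xd.W + 2 * pw - kW) / sw + 1;
  const long long N = (long long)To * Ho * Wo;
  const long long ckv = (long long)Ci * kT * kH * kW;

  NumericVector y(Co * N * xd.B);
  arma::mat Wm(const_cast<double *>(w.begin()), Co, ckv, false, true);
  long long chunk = std::max(1LL, COL_BUDGET / ckv);
  arma::mat col(ckv, std::min(chunk, N));
  const bool has_bias = bias.size() > 0;
  arma::vec bv = has_bias ? arma::vec(bias.begin(), Co) : arma::vec();

  for (int b = 0; b < xd.B; ++b) {
    const double *xb = x.begin() + (long long)b * xd.C * xd.T * xd.H * xd.W;
    arma::mat Y(y.begin() + (long long)b * Co * N, Co, N, false, true);
    for (long long p0 = 0; p0 < N; p0 += chunk) {
      long long p1 = std::min(p0 + chunk, N);
      arma::mat cc = col.cols(0, p1 - p0 - 1);
      im2col_chunk(xb, xd, To, Ho, Wo, kT, kH, kW, st, sh, sw, pt, ph, pw, p0, p1, cc);
      Y.cols(p0, p1 - 1) = Wm * cc;
    }
    if (has_bias) Y.each_col() += bv;
  }
  y.attr("dim") = IntegerVector::create(Co, To, Ho, Wo, xd.B);
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector xdim,
                    NumericVector w, IntegerVector wdim,
                    NumericVector dy,
                    IntegerVector stride, IntegerVector pad,
                    bool need_dx) {
  Dims xd = get_dims(xdim);
  const int Co = wdim[0], Ci = wdim[1], kT = wdim[2], kH = wdim[3], kW = wdim[4];
  const int st = stride[0], sh = stride[1], sw = stride[2];
  const int pt = pad[0], ph = pad[1], pw = pad[2];
  const int To = (xd.T + 2 * pt - kT) / st + 1;
  const int Ho = (xd.H + 2 * ph - kH) / sh + 1;
  const int Wo = (xd.W + 2 * pw - kW) / sw + 1;
  const long long N = (long long)To * Ho * Wo;
  const long long ckv = (long long)Ci * kT * kH * kW;

  arma::mat Wm(const_cast<double *>(w.begin()), Co, ckv, false, true);
  NumericVector dwv(w.size());
  arma::mat dW(dwv.begin(), Co, ckv, false, true);
  NumericVector dbv(Co);
  arma::vec db(dbv.begin(), Co, false, true);
  NumericVector dxv(need_dx ? x.size() : 0);

  long long chunk = std::max(1LL, COL_BUDGET / ckv);
  arma::mat col(ckv, std::min(chunk, N));

  for (int b = 0; b < xd.B; ++b) {
    const double *xb = x.begin() + (long long)b * xd.C * xd.T * xd.H * xd.W;
    arma::mat dY(const_cast<double *>(dy.begin()) + (long long)b * Co * N, Co, N, false, true);
    double *dxb = need_dx ? dxv.begin() + (long long)b * xd.C * xd.T * xd.H * xd.W : nullptr;
    for (long long p0 = 0; p0 < N; p0 += chunk) {
      long long p1 = std::min(p0 + chunk, N);
      arma::mat cc = col.cols(0, p1 - p0 - 1);
      im2col_chunk(xb, xd, To, Ho, Wo, kT, kH, kW, st, sh, sw, pt, ph, pw, p0, p1, cc);
      arma::mat dYc = dY.cols(p0, p1 - 1);
      dW += dYc * cc.t();
      if (need_dx) {
        arma::mat dcol = Wm.t() * dYc;
        col2im_chunk(dcol, dxb, xd, To, Ho, Wo, kT, kH, kW, st, sh, sw, pt, ph, pw, p0, p1);
      }
    }
    db += arma::sum(dY, 1);
  }
  dwv.attr("dim") = wdim;
  if (need_dx) dxv.attr("dim") = xdim;
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// Build the (Co*kv) x Ci matrix used by the transposed convolution, with rows
// ordered (co, kt, kh, kw), co fastest.
static arma::mat transpose_weight(const double *w, int Co, int Ci, int kT, int kH, int kW) {
  const long long kv = (long long)kT * kH * kW;
  arma::mat Wt(Co * kv, Ci);
  for (int ci = 0; ci < Ci; ++ci)
    for (long long k = 0; k < kv; ++k)
      for (int co = 0; co < Co; ++co)
        Wt(co + Co * k, ci) = w[co + (long long)Co * ci + (long long)Co * Ci * k];
  return Wt;
}

// [[Rcpp::export]]
NumericVector cpp_convt3d_fwd(NumericVector x, IntegerVector xdim,
                              NumericVector w, IntegerVector wdim,
                              NumericVector bias,
                              IntegerVector stride, IntegerVector pad) {
  Dims xd = get_dims(xdim);
  const int Co = wdim[0], Ci = wdim[1], kT = wdim[2], kH = wdim[3], kW = wdim[4];
  if (Ci != xd.C) stop("conv_transpose3d: input has %d channels, weights expect %d", xd.C, Ci);
  const int st = stride[0], sh = stride[1], sw = stride[2];
  const int pt = pad[0], ph = pad[1], pw = pad[2];
  const int To = (xd.T - 1) * st - 2 * pt + kT;
  const int Ho = (xd.H - 1) * sh - 2 * ph + kH;
  const int Wo = (xd.W - 1) * sw - 2 * pw + kW;
  const long long Nin = (long long)xd.T * xd.H * xd.W;
  const long long Nout = (long long)To * Ho * Wo;
  const long long rows = (long long)Co * kT * kH * kW;

  arma::mat Wt = transpose_weight(w.begin(), Co, Ci, kT, kH, kW);
  NumericVector y(Co * Nout * xd.B);
  Dims yd; yd.C = Co; yd.T = To; yd.H = Ho; yd.W = Wo; yd.B = xd.B;
  long long chunk = std::max(1LL, COL_BUDGET / rows);
  const bool has_bias = bias.size() > 0;

  for (int b = 0; b < xd.B; ++b) {
    arma::mat X(const_cast<double *>(x.begin()) + (long long)b * Ci * Nin, Ci, Nin, false, true);
    double *yb = y.begin() + (long long)b * Co * Nout;
    for (long long p0 = 0; p0 < Nin; p0 += chunk) {
      long long p1 = std::min(p0 + chunk, Nin);
      arma::mat scat = Wt * X.cols(p0, p1 - 1); // (Co*kv) x n
      for (long long p = p0; p < p1; ++p) {
        long long q = p;
        const int it = (int)(q % xd.T); q /= xd.T;
        const int ih = (int)(q % xd.H); q /= xd.H;
        const int iw = (int)q;
        const double *src = scat.colptr(p - p0);
        for (int kw = 0; kw < kW; ++kw) {
          const int ow = iw * sw - pw + kw;
          if (ow < 0 || ow >= Wo) continue;
          for (int kh = 0; kh < kH; ++kh) {
            const int oh = ih * sh - ph + kh;
            if (oh < 0 || oh >= Ho) continue;
            for (int kt = 0; kt < kT; ++kt) {
              const int ot = it * st - pt + kt;
              if (ot < 0 || ot >= To) continue;
              const double *s = src + (long long)Co * (kt + (long long)kT * (kh + (long long)kH * kw));
              double *d = yb + idx4(0, ot, oh, ow, yd);
              for (int co = 0; co < Co; ++co) d[co] += s[co];
            }
          }
        }
      }
    }
    if (has_bias) {
      arma::mat Y(yb, Co, Nout, false, true);
      Y.each_col() += arma::vec(bias.begin(), Co);
    }
  }
  y.attr("dim") = IntegerVector::create(Co, To, Ho, Wo, xd.B);
  return y;
}

// [[Rcpp::export]]
List cpp_convt3d_bwd(NumericVector x, IntegerVector xdim,
                     NumericVector w, IntegerVector wdim,
                     NumericVector dy,
                     IntegerVector stride, IntegerVector pad,
                     bool need_dx) {
  Dims xd = get_dims(xdim);
  const int Co = wdim[0], Ci = wdim[1], kT = wdim[2], kH = wdim[3], kW = wdim[4];
  const int st = stride[0], sh = stride[1], sw = stride[2];
  const int pt = pad[0], ph = pad[1], pw = pad[2];
  const int To = (xd.T - 1) * st - 2 * pt + kT;
  const int Ho = (xd.H - 1) * sh - 2 * ph + kH;
  const int Wo = (xd.W - 1) * sw - 2 * pw + kW;
  const long long Nin = (long long)xd.T * xd.H * xd.W;
  const long long Nout = (long long)To * Ho * Wo;
  const long long rows = (long long)Co * kT * kH * kW;
  const long long kv = (long long)kT * kH * kW;
  Dims yd; yd.C = Co; yd.T = To; yd.H = Ho; yd.W = Wo; yd.B = xd.B;

  arma::mat Wt = transpose_weight(w.begin(), Co, Ci, kT, kH, kW);
  arma::mat dWt(rows, Ci, arma::fill::zeros);
  NumericVector dbv(Co);
  arma::vec db(dbv.begin(), Co, false, true);
  NumericVector dxv(need_dx ? x.size() : 0);
  long long chunk = std::max(1LL, COL_BUDGET / rows);
  arma::mat col(rows, std::min(chunk, Nin));

  for (int b = 0; b < xd.B; ++b) {
    const double *dyb = dy.begin() + (long long)b * Co * Nout;
    arma::mat X(const_cast<double *>(x.begin()) + (long long)b * Ci * Nin, Ci, Nin, false, true);
    for (long long p0 = 0; p0 < Nin; p0 += chunk) {
      long long p1 = std::min(p0 + chunk, Nin);
      arma::mat cc = col.cols(0, p1 - p0 - 1);
      cc.zeros();
      // gather the dy values each input position scattered to
      for (long long p = p0; p < p1; ++p) {
        long long q = p;
        const int it = (int)(q % xd.T); q /= xd.T;
        const int ih = (int)(q % xd.H); q /= xd.H;
        const int iw = (int)q;
        double *dst = cc.colptr(p - p0);
        for (int kw = 0; kw < kW; ++kw) {
          const int ow = iw * sw - pw + kw;
          if (ow < 0 || ow >= Wo) continue;
          for (int kh = 0; kh < kH; ++kh) {
            const int oh = ih * sh - ph + kh;
            if (oh < 0 || oh >= Ho) continue;
            for (int kt = 0; kt < kT; ++kt) {
              const int ot = it * st - pt + kt;
              if (ot < 0 || ot >= To) continue;
              const double *s = dyb + idx4(0, ot, oh, ow, yd);
              double *d = dst + (long long)Co * (kt + (long long)kT * (kh + (long long)kH * kw));
              std::copy(s, s + Co, d);
            }
          }
        }
      }
      dWt += cc * X.cols(p0, p1 - 1).t();
      if (need_dx) {
        arma::mat dX = Wt.t() * cc; // Ci x n
        std::copy(dX.begin(), dX.end(),
                  dxv.begin() + (long long)b * Ci * Nin + (long long)Ci * p0);
      }
    }
    arma::mat dY(const_cast<double *>(dyb), Co, Nout, false, true);
    db += arma::sum(dY, 1);
  }
  // un-permute dWt (rows = co + Co*k) back to weight layout (Co, Ci, k)
  NumericVector dwv(w.size());
  for (int ci = 0; ci < Ci; ++ci)
    for (long long k = 0; k < kv; ++k)
      for (int co = 0; co < Co; ++co)
        dwv[co + (long long)Co * ci + (long long)Co * Ci * k] = dWt(co + Co * k, ci);
  dwv.attr("dim") = wdim;
  if (need_dx) dxv.attr("dim") = xdim;
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// [[Rcpp::export]]
List cpp_maxpool3d_fwd(NumericVector x, IntegerVector xdim, IntegerVector pool) {
  Dims xd = get_dims(xdim);
  const int ptl = pool[0], ph = pool[1], pw = pool[2];
  if (xd.T % ptl || xd.H % ph || xd.W % pw)
    stop("maxpool3d: dimensions (%d,%d,%d) not divisible by pool (%d,%d,%d)",
         xd.T, xd.H, xd.W, ptl, ph, pw);
  const int To = xd.T / ptl, Ho = xd.H / ph, Wo = xd.W / pw;
  const long long Nout = (long long)xd.C * To * Ho * Wo;
  NumericVector y(Nout * xd.B);
  IntegerVector idx(Nout * xd.B);
  for (int b = 0; b < xd.B; ++b) {
    const double *xb = x.begin() + (long long)b * xd.C * xd.T * xd.H * xd.W;
    double *yb = y.begin() + (long long)b * Nout;
    int *ib = idx.begin() + (long long)b * Nout;
    long long o = 0;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int to = 0; to < To; ++to)
          for (int c = 0; c < xd.C; ++c) {
            double best = -std::numeric_limits<double>::infinity();
            long long besti = -1;
            for (int dw = 0; dw < pw; ++dw)
              for (int dh = 0; dh < ph; ++dh)
                for (int dt = 0; dt < ptl; ++dt) {
                  long long ii = idx4(c, to * ptl + dt, ho * ph + dh, wo * pw + dw, xd);
                  if (xb[ii] > best) { best = xb[ii]; besti = ii; }
                }
            // output laid out (C, To, Ho, Wo)
            long long oo = c + (long long)xd.C * (to + (long long)To * (ho + (long long)Ho * wo));
            yb[oo] = best; ib[oo] = (int)besti; ++o;
          }
  }
  y.attr("dim") = IntegerVector::create(xd.C, To, Ho, Wo, xd.B);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bwd(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  Dims xd = get_dims(xdim);
  const long long clip = (long long)xd.C * xd.T * xd.H * xd.W;
  NumericVector dx(clip * xd.B);
  const long long Nout = dy.size() / xd.B;
  for (int b = 0; b < xd.B; ++b) {
    const double *dyb = dy.begin() + b * Nout;
    const int *ib = idx.begin() + b * Nout;
    double *dxb = dx.begin() + b * clip;
    for (long long o = 0; o < Nout; ++o) dxb[ib[o]] += dyb[o];
  }
  dx.attr("dim") = xdim;
  return dx;
}

// Bilinear resize of a frame sequence stored as (T, H, W, C); pixel-centre
// (half-pixel) alignment, matching the usual image-resize convention.
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector x, IntegerVector xdim,
                                  int Ho, int Wo) {
  const int T = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  NumericVector y((long long)T * Ho * Wo * C);
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo) {
      double fw = (wo + 0.5) * sw - 0.5;
      int w0 = (int)std::floor(fw);
      double aw = fw - w0;
      int w0c = std::min(std::max(w0, 0), W - 1);
      int w1c = std::min(std::max(w0 + 1, 0), W - 1);
      for (int ho = 0; ho < Ho; ++ho) {
        double fh = (ho + 0.5) * sh - 0.5;
        int h0 = (int)std::floor(fh);
        double ah = fh - h0;
        int h0c = std::min(std::max(h0, 0), H - 1);
        int h1c = std::min(std::max(h0 + 1, 0), H - 1);
        for (int t = 0; t < T; ++t) {
          const double *xb = x.begin() + t + (long long)T * 0;
          double v00 = x[t + (long long)T * (h0c + (long long)H * (w0c + (long long)W * c))];
          double v10 = x[t + (long long)T * (h1c + (long long)H * (w0c + (long long)W * c))];
          double v01 = x[t + (long long)T * (h0c + (long long)H * (w1c + (long long)W * c))];
          double v11 = x[t + (long long)T * (h1c + (long long)H * (w1c + (long long)W * c))];
          (void)xb;
          y[t + (long long)T * (ho + (long long)Ho * (wo + (long long)Wo * c))] =
            (1 - ah) * ((1 - aw) * v00 + aw * v01) + ah * ((1 - aw) * v10 + aw * v11);
        }
      }
    }
  y.attr("dim") = IntegerVector::create(T, Ho, Wo, C);
  return y;
}
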