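// Convolutional primitives for the dense-regression networks.
// Array layout (column-major, matching R):
//   2D feature maps: (H, W, C, N)
//   3D feature maps: (Dp, H, W, C, N)  -- Dp is the spatial-frequency axis
// Weights: conv2d (kh, kw, Ci, Co); conv3d (kd, kh, kw, Ci, Co).
// All convolutions are stride 1 with same (zero) padding; pooling is 2x2
// stride 2 with floor sizing; upsampling is nearest-neighbour to an
// explicit target size. im2col matrices are built for the whole batch so
// each layer costs a single GEMM.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static void im2col2d(const double *x, uword H, uword W, uword C,
                     uword kh, uword kw, mat &col, uword colOffset) {
  const sword ph = (sword)(kh / 2), pw = (sword)(kw / 2);
  const uword R = col.n_rows;
  // position-major: each output position owns one contiguous column
  for (uword w = 0; w < W; ++w) {
    for (uword h = 0; h < H; ++h) {
      double *dst = col.memptr() + R * (colOffset + w * H + h);
      for (uword c = 0; c < C; ++c) {
        const double *xc = x + c * H * W;
        for (uword dw = 0; dw < kw; ++dw) {
          sword iw = (sword)w + (sword)dw - pw;
          uword r0 = kh * (dw + kw * c);
          if (iw < 0 || iw >= (sword)W) {
            for (uword dh = 0; dh < kh; ++dh) dst[r0 + dh] = 0.0;
            continue;
          }
          const double *src = xc + (uword)iw * H;
          for (uword dh = 0; dh < kh; ++dh) {
            sword ih = (sword)h + (sword)dh - ph;
            dst[r0 + dh] = (ih < 0 || ih >= (sword)H) ? 0.0 : src[ih];
          }
        }
      }
    }
  }
}

static void col2im2d(const mat &col, uword colOffset, uword H, uword W,
                     uword C, uword kh, uword kw, double *dx) {
  const sword ph = (sword)(kh / 2), pw = (sword)(kw / 2);
  const uword R = col.n_rows;
  for (uword w = 0; w < W; ++w) {
    for (uword h = 0; h < H; ++h) {
      const double *src = col.memptr() + R * (colOffset + w * H + h);
      for (uword c = 0; c < C; ++c) {
        double *xc = dx + c * H * W;
        for (uword dw = 0; dw < kw; ++dw) {
          sword iw = (sword)w + (sword)dw - pw;
          if (iw < 0 || iw >= (sword)W) continue;
          uword r0 = kh * (dw + kw * c);
          double *dstc = xc + (uword)iw * H;
          for (uword dh = 0; dh < kh; ++dh) {
            sword ih = (sword)h + (sword)dh - ph;
            if (ih >= 0 && ih < (sword)H) dstc[ih] += src[r0 + dh];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2dForwardCpp")]]
Rcpp::NumericVector conv2d_forward(const Rcpp::NumericVector &xv,
                                   const Rcpp::NumericVector &wv,
                                   const Rcpp::NumericVector &bv) {
  Rcpp::IntegerVector xd = xv.attr("dim"), wd = wv.attr("dim");
  const uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const uword kh = wd[0], kw = wd[1], Co = wd[3];
  const uword HW = H * W;
  mat Wm(const_cast<double *>(wv.begin()), kh * kw * C, Co, false, true);
  vec b(const_cast<double *>(bv.begin()), Co, false, true);
  Rcpp::NumericVector yv(HW * Co * N);
  yv.attr("dim") = Rcpp::IntegerVector::create(H, W, Co, N);
  mat col(kh * kw * C, HW * N);
  for (uword n = 0; n < N; ++n)
    im2col2d(xv.begin() + n * HW * C, H, W, C, kh, kw, col, n * HW);
  mat Y = col.t() * Wm;            // (HW*N) x Co, sample-major rows
  Y.each_row() += b.t();
  for (uword n = 0; n < N; ++n) {
    mat y(yv.begin() + n * HW * Co, HW, Co, false, true);
    y = Y.rows(n * HW, (n + 1) * HW - 1);
  }
  return yv;
}

// [[Rcpp::export(name = ".conv2dBackwardCpp")]]
Rcpp::List conv2d_backward(const Rcpp::NumericVector &xv,
                           const Rcpp::NumericVector &wv,
                           const Rcpp::NumericVector &dyv) {
  Rcpp::IntegerVector xd = xv.attr("dim"), wd = wv.attr("dim");
  const uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const uword kh = wd[0], kw = wd[1], Co = wd[3];
  const uword HW = H * W;
  mat Wm(const_cast<double *>(wv.begin()), kh * kw * C, Co, false, true);
  Rcpp::NumericVector dxv(xv.size());
  dxv.attr("dim") = xd;
  Rcpp::NumericVector dwv(wv.size());
  dwv.attr("dim") = wd;
  Rcpp::NumericVector dbv(Co);
  mat dWm(dwv.begin(), kh * kw * C, Co, false, true);
  vec db(dbv.begin(), Co, false, true);
  mat col(kh * kw * C, HW * N);
  mat dY(HW * N, Co);
  for (uword n = 0; n < N; ++n) {
    im2col2d(xv.begin() + n * HW * C, H, W, C, kh, kw, col, n * HW);
    dY.rows(n * HW, (n + 1) * HW - 1) =
        mat(const_cast<double *>(dyv.begin()) + n * HW * Co, HW, Co,
            false, true);
  }
  dWm = col * dY;
  db = sum(dY, 0).t();
  mat dcol = Wm * dY.t();          // (kh*kw*C) x (HW*N)
  for (uword n = 0; n < N; ++n)
    col2im2d(dcol, n * HW, H, W, C, kh, kw, dxv.begin() + n * HW * C);
  return Rcpp::List::create(Rcpp::Named("dx") = dxv,
                            Rcpp::Named("dw") = dwv,
                            Rcpp::Named("db") = dbv);
}

// extract the (kh, kw, Ci, Co) sub-kernel of frequency tap dd from a
// (kd, kh, kw, Ci, Co) conv3d weight tensor
static mat packTap(const double *wptr, uword kd, uword kh, uword kw,
                   uword C, uword Co, uword dd) {
  mat Wdd(kh * kw * C, Co);
  for (uword co = 0; co < Co; ++co)
    for (uword c = 0; c < C; ++c)
      for (uword dw = 0; dw < kw; ++dw)
        for (uword dh = 0; dh < kh; ++dh)
          Wdd(dh + kh * (dw + kw * c), co) =
              wptr[dd + kd * (dh + kh * (dw + kw * (c + C * co)))];
  return Wdd;
}

// gather frequency slice s of (Dp, H, W, C, N) into contiguous (H, W, C, N)
static void gatherSlice(const double *x, uword Dp, uword HWC_N, uword s,
                        double *xs) {
  for (uword i = 0; i < HWC_N; ++i) xs[i] = x[s + Dp * i];
}

// conv3d is evaluated per frequency slice: one 2D im2col per slice plus a
// small GEMM per (output frequency, kernel tap) pair
// [[Rcpp::export(name = ".conv3dForwardCpp")]]
Rcpp::NumericVector conv3d_forward(const Rcpp::NumericVector &xv,
                                   const Rcpp::NumericVector &wv,
                                   const Rcpp::NumericVector &bv) {
  Rcpp::IntegerVector xd = xv.attr("dim"), wd = wv.attr("dim");
  const uword Dp = xd[0], H = xd[1], W = xd[2], C = xd[3], N = xd[4];
  const uword kd = wd[0], kh = wd[1], kw = wd[2], Co = wd[4];
  const uword DHW = Dp * H * W, HW = H * W, HWN = HW * N;
  const sword pd = (sword)(kd / 2);
  vec b(const_cast<double *>(bv.begin()), Co, false, true);
  Rcpp::NumericVector yv(DHW * Co * N);
  yv.attr("dim") = Rcpp::IntegerVector::create(Dp, H, W, Co, N);
  std::vector<mat> taps(kd);
  for (uword dd = 0; dd < kd; ++dd)
    taps[dd] = packTap(wv.begin(), kd, kh, kw, C, Co, dd);
  std::vector<mat> cols(Dp);
  vec xs(HW * C * N);
  for (uword s = 0; s < Dp; ++s) {
    for (uword n = 0; n < N; ++n)
      gatherSlice(xv.begin() + n * DHW * C, Dp, HW * C, s,
                  xs.memptr() + n * HW * C);
    cols[s].set_size(kh * kw * C, HWN);
    for (uword n = 0; n < N; ++n)
      im2col2d(xs.memptr() + n * HW * C, H, W, C, kh, kw, cols[s], n * HW);
  }
  mat Yd(HWN, Co);
  for (uword d = 0; d < Dp; ++d) {
    Yd.zeros();
    for (uword dd = 0; dd < kd; ++dd) {
      sword s = (sword)d + (sword)dd - pd;
      if (s < 0 || s >= (sword)Dp) continue;
      Yd += cols[(uword)s].t() * taps[dd];
    }
    Yd.each_row() += b.t();
    // scatter (sample-major rows) into the (Dp, H, W, Co, N) output
    for (uword n = 0; n < N; ++n)
      for (uword co = 0; co < Co; ++co) {
        double *yp = yv.begin() + d + Dp * (HW * (co + Co * n));
        const double *src = Yd.colptr(co) + n * HW;
        for (uword i = 0; i < HW; ++i) yp[Dp * i] = src[i];
      }
  }
  return yv;
}

// [[Rcpp::export(name = ".conv3dBackwardCpp")]]
Rcpp::List conv3d_backward(const Rcpp::NumericVector &xv,
                           const Rcpp::NumericVector &wv,
                           const Rcpp::NumericVector &dyv) {
  Rcpp::IntegerVector xd = xv.attr("dim"), wd = wv.attr("dim");
  const uword Dp = xd[0], H = xd[1], W = xd[2], C = xd[3], N = xd[4];
  const uword kd = wd[0], kh = wd[1], kw = wd[2], Co = wd[4];
  const uword DHW = Dp * H * W, HW = H * W, HWN = HW * N;
  const sword pd = (sword)(kd / 2);
  Rcpp::NumericVector dxv(xv.size());
  dxv.attr("dim") = xd;
  Rcpp::NumericVector dwv(wv.size());
  dwv.attr("dim") = wd;
  Rcpp::NumericVector dbv(Co);
  vec db(dbv.begin(), Co, false, true);
  std::vector<mat> taps(kd), dtaps(kd);
  for (uword dd = 0; dd < kd; ++dd) {
    taps[dd] = packTap(wv.begin(), kd, kh, kw, C, Co, dd);
    dtaps[dd].zeros(kh * kw * C, Co);
  }
  // gather all output-frequency gradients as (HWN x Co) matrices
  std::vector<mat> dYs(Dp);
  for (uword d = 0; d < Dp; ++d) {
    dYs[d].set_size(HWN, Co);
    for (uword n = 0; n < N; ++n)
      for (uword co = 0; co < Co; ++co) {
        const double *dp_ = dyv.begin() + d + Dp * (HW * (co + Co * n));
        double *dst = dYs[d].colptr(co) + n * HW;
        for (uword i = 0; i < HW; ++i) dst[i] = dp_[Dp * i];
      }
    db += sum(dYs[d], 0).t();
  }
  mat col(kh * kw * C, HWN);
  vec xs(HW * C * N), dxs(HW * C * N);
  for (uword s = 0; s < Dp; ++s) {
    for (uword n = 0; n < N; ++n)
      gatherSlice(xv.begin() + n * DHW * C, Dp, HW * C, s,
                  xs.memptr() + n * HW * C);
    for (uword n = 0; n < N; ++n)
      im2col2d(xs.memptr() + n * HW * C, H, W, C, kh, kw, col, n * HW);
    mat dcol(kh * kw * C, HWN, fill::zeros);
    bool any = false;
    for (uword dd = 0; dd < kd; ++dd) {
      sword d = (sword)s - (sword)dd + pd;
      if (d < 0 || d >= (sword)Dp) continue;
      dtaps[dd] += col * dYs[(uword)d];
      dcol += taps[dd] * dYs[(uword)d].t();
      any = true;
    }
    if (!any) continue;
    dxs.zeros();
    for (uword n = 0; n < N; ++n)
      col2im2d(dcol, n * HW, H, W, C, kh, kw, dxs.memptr() + n * HW * C);
    for (uword n = 0; n < N; ++n) {
      double *dxp = dxv.begin() + n * DHW * C;
      const double *src = dxs.memptr() + n * HW * C;
      for (uword i = 0; i < HW * C; ++i) dxp[s + Dp * i] += src[i];
    }
  }
  // scatter tap gradients back into the (kd, kh, kw, Ci, Co) tensor
  for (uword dd = 0; dd < kd; ++dd)
    for (uword co = 0; co < Co; ++co)
      for (uword c = 0; c < C; ++c)
        for (uword dw = 0; dw < kw; ++dw)
          for (uword dh = 0; dh < kh; ++dh)
            dwv[dd + kd * (dh + kh * (dw + kw * (c + C * co)))] =
                dtaps[dd](dh + kh * (dw + kw * c), co);
  return Rcpp::List::create(Rcpp::Named("dx") = dxv,
                            Rcpp::Named("dw") = dwv,
                            Rcpp::Named("db") = dbv);
}

// [[Rcpp::export(name = ".maxpool2ForwardCpp")]]
Rcpp::List maxpool2_forward(const Rcpp::NumericVector &xv) {
  Rcpp::IntegerVector xd = xv.attr("dim");
  const uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const uword Ho = H / 2, Wo = W / 2;
  Rcpp::NumericVector yv(Ho * Wo * C * N);
  yv.attr("dim") = Rcpp::IntegerVector::create(Ho, Wo, C, N);
  Rcpp::IntegerVector av(yv.size());  // linear argmax into x
  const double *x = xv.begin();
  double *y = yv.begin();
  int *am = av.begin();
  for (uword nc = 0; nc < C * N; ++nc) {
    const double *xc = x + nc * H * W;
    uword base = nc * H * W;
    for (uword w = 0; w < Wo; ++w)
      for (uword h = 0; h < Ho; ++h) {
        uword i00 = (2 * w) * H + 2 * h;
        uword best = i00;
        double v = xc[i00];
        uword cand[3] = {i00 + 1, i00 + H, i00 + H + 1};
        for (int t = 0; t < 3; ++t)
          if (xc[cand[t]] > v) { v = xc[cand[t]]; best = cand[t]; }
        uword oi = (nc * Wo + w) * Ho + h;
        y[oi] = v;
        am[oi] = (int)(base + best);
      }
  }
  return Rcpp::List::create(Rcpp::Named("y") = yv, Rcpp::Named("argmax") = av);
}

// [[Rcpp::export(name = ".maxpool2BackwardCpp")]]
Rcpp::NumericVector maxpool2_backward(const Rcpp::NumericVector &dyv,
                                      const Rcpp::IntegerVector &av,
                                      const Rcpp::IntegerVector &xdim) {
  uword n = 1;
  for (int i = 0; i < xdim.size(); ++i) n *= (uword)xdim[i];
  Rcpp::NumericVector dxv(n);
  dxv.attr("dim") = xdim;
  double *dx = dxv.begin();
  const double *dy = dyv.begin();
  const int *am = av.begin();
  for (R_xlen_t i = 0; i < dyv.size(); ++i) dx[am[i]] += dy[i];
  return dxv;
}

// [[Rcpp::export(name = ".upsampleForwardCpp")]]
Rcpp::NumericVector upsample_forward(const Rcpp::NumericVector &xv,
                                     int Ho, int Wo) {
  Rcpp::IntegerVector xd = xv.attr("dim");
  const uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  Rcpp::NumericVector yv((uword)Ho * Wo * C * N);
  yv.attr("dim") = Rcpp::IntegerVector::create(Ho, Wo, C, N);
  const double *x = xv.begin();
  double *y = yv.begin();
  for (uword nc = 0; nc < C * N; ++nc) {
    const double *xc = x + nc * H * W;
    double *yc = y + nc * (uword)Ho * Wo;
    for (int w = 0; w < Wo; ++w) {
      uword iw = (uword)((long long)w * W / Wo);
      for (int h = 0; h < Ho; ++h) {
        uword ih = (uword)((long long)h * H / Ho);
        yc[(uword)w * Ho + h] = xc[iw * H + ih];
      }
    }
  }
  return yv;
}

// [[Rcpp::export(name = ".upsampleBackwardCpp")]]
Rcpp::NumericVector upsample_backward(const Rcpp::NumericVector &dyv,
                                      const Rcpp::IntegerVector &xdim) {
  const uword H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  Rcpp::IntegerVector yd = dyv.attr("dim");
  const uword Ho = yd[0], Wo = yd[1];
  Rcpp::NumericVector dxv(H * W * C * N);
  dxv.attr("dim") = xdim;
  double *dx = dxv.begin();
  const double *dy = dyv.begin();
  for (uword nc = 0; nc < C * N; ++nc) {
    const double *dyc = dy + nc * Ho * Wo;
    double *dxc = dx + nc * H * W;
    for (uword w = 0; w < Wo; ++w) {
      uword iw = w * W / Wo;
      for (uword h = 0; h < Ho; ++h) {
        uword ih = h * H / Ho;
        dxc[iw * H + ih] += dyc[w * Ho + h];
      }
    }
  }
  return dxv;
}
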