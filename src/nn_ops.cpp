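// Compiled kernels for the CNN engine: 3x3 same-padding convolution
// (im2col + BLAS through Armadillo) and 2x2 max-pooling, channels-first
// (C, H, W, N) layout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// One sample's im2col: columns indexed by (y, x); rows by (k, c) with c
// fastest per offset k. Buffer stays cache-resident for miniature layers.
static void im2col3_one(const double *xn, int C, int H, int W,
                        arma::mat &cols) {
  for (int k = 0; k < 9; ++k) {
    const int dy = k % 3 - 1, dx = k / 3 - 1;
    const int r0 = k * C;
    for (int xx = 0; xx < W; ++xx) {
      const int sx = xx + dx;
      for (int yy = 0; yy < H; ++yy) {
        const int sy = yy + dy;
        double *dst = cols.colptr(yy + (long)H * xx) + r0;
        if (sx < 0 || sx >= W || sy < 0 || sy >= H) {
          std::memset(dst, 0, C * sizeof(double));
        } else {
          std::memcpy(dst, xn + (long)C * (sy + (long)H * sx),
                      C * sizeof(double));
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, IntegerVector xdim,
                           NumericMatrix Wm, NumericVector b) {
  const int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  const int Cout = Wm.nrow();
  const long HW = (long)H * W;
  NumericVector res((long)Cout * HW * N);
  arma::mat Wa(Wm.begin(), Cout, 9 * C, false);
  arma::vec bv(b.begin(), Cout, false);
  arma::mat cols(9 * C, HW);
  for (int n = 0; n < N; ++n) {
    im2col3_one(x.begin() + (long)C * HW * n, C, H, W, cols);
    arma::mat outn(res.begin() + (long)Cout * HW * n, Cout, HW, false, true);
    outn = Wa * cols;
    outn.each_col() += bv;
  }
  res.attr("dim") = IntegerVector::create(Cout, H, W, N);
  return res;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector dout, NumericVector x, IntegerVector xdim,
                  NumericMatrix Wm, bool need_gw, bool need_dx) {
  const int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  const int Cout = Wm.nrow();
  const long HW = (long)H * W;
  arma::mat Wa(Wm.begin(), Cout, 9 * C, false);
  arma::mat gW(Cout, 9 * C, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  NumericVector dx;
  double *dxp = NULL;
  if (need_dx) {
    dx = NumericVector((long)C * HW * N);
    dxp = dx.begin();
  }
  arma::mat cols(9 * C, HW);
  arma::mat dcols(9 * C, HW);
  for (int n = 0; n < N; ++n) {
    arma::mat dmn(const_cast<double *>(dout.begin()) + (long)Cout * HW * n,
                  Cout, HW, false);
    if (need_gw) {
      im2col3_one(x.begin() + (long)C * HW * n, C, H, W, cols);
      gW += dmn * cols.t();
      gb += arma::sum(dmn, 1);
    }
    if (need_dx) {
      dcols = Wa.t() * dmn;
      double *dxn = dxp + (long)C * HW * n;
      for (int k = 0; k < 9; ++k) {
        const int dy = k % 3 - 1, dx_ = k / 3 - 1;
        const int r0 = k * C;
        for (int xx = 0; xx < W; ++xx) {
          const int sx = xx + dx_;
          if (sx < 0 || sx >= W) continue;
          for (int yy = 0; yy < H; ++yy) {
            const int sy = yy + dy;
            if (sy < 0 || sy >= H) continue;
            const double *src = dcols.colptr(yy + (long)H * xx) + r0;
            double *dst = dxn + (long)C * (sy + (long)H * sx);
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  List res;
  if (need_gw) {
    res["gW"] = NumericMatrix(Cout, 9 * C, gW.begin());
    res["gb"] = NumericVector(gb.begin(), gb.end());
  }
  if (need_dx) {
    dx.attr("dim") = IntegerVector::create(C, H, W, N);
    res["dx"] = dx;
  }
  return res;
}

// [[Rcpp::export]]
List cpp_pool_fwd(NumericVector x, IntegerVector xdim) {
  const int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  const long no = (long)C * Ho * Wo * N;
  NumericVector out(no);
  RawVector which(no);
  const double *xp = x.begin();
  double *op = out.begin();
  unsigned char *wp = (unsigned char *)RAW(which);
  const long HW = (long)H * W;
  for (int n = 0; n < N; ++n) {
    for (int ox = 0; ox < Wo; ++ox) {
      for (int oy = 0; oy < Ho; ++oy) {
        const long base = (long)C * (2 * oy + (long)H * (2 * ox)
                                     + HW * n);
        const double *p1 = xp + base;                       // (2oy, 2ox)
        const double *p2 = xp + base + (long)C * H;         // (2oy, 2ox+1)
        const double *p3 = xp + base + C;                   // (2oy+1, 2ox)
        const double *p4 = xp + base + (long)C * H + C;     // (2oy+1, 2ox+1)
        const long obase = (long)C * (oy + (long)Ho * ox
                                      + (long)Ho * Wo * n);
        for (int c = 0; c < C; ++c) {
          // deterministic first-match order: TL, TR, BL, BR in (y,x)
          double m = p1[c]; unsigned char w = 1;
          if (p3[c] > m) { m = p3[c]; w = 2; }
          if (p2[c] > m) { m = p2[c]; w = 3; }
          if (p4[c] > m) { m = p4[c]; w = 4; }
          op[obase + c] = m;
          wp[obase + c] = w;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  return List::create(_["out"] = out, _["which"] = which);
}

// [[Rcpp::export]]
NumericVector cpp_pool_bwd(NumericVector dout, RawVector which,
                           IntegerVector xdim) {
  const int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx((long)C * H * W * N);
  double *dxp = dx.begin();
  const double *dp = dout.begin();
  const unsigned char *wp = (const unsigned char *)RAW(which);
  const long HW = (long)H * W;
  for (int n = 0; n < N; ++n) {
    for (int ox = 0; ox < Wo; ++ox) {
      for (int oy = 0; oy < Ho; ++oy) {
        const long base = (long)C * (2 * oy + (long)H * (2 * ox) + HW * n);
        const long obase = (long)C * (oy + (long)Ho * ox
                                      + (long)Ho * Wo * n);
        for (int c = 0; c < C; ++c) {
          long off;
          switch (wp[obase + c]) {
          case 1: off = base + c; break;
          case 2: off = base + C + c; break;
          case 3: off = base + (long)C * H + c; break;
          default: off = base + (long)C * H + C + c;
          }
          dxp[off] += dp[obase + c];
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(C, H, W, N);
  return dx;
}
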