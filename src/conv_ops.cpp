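// 2-D convolution forward/backward kernels for the reconstruction networks.
// Tensors are R arrays in column-major (H, W, C, N) layout; weights are
// (k, k, Cin, Cout).  Convolutions use im2col + BLAS GEMM, zero padding,
// arbitrary stride.  No deep-learning framework exists in this R stack, so
// these primitives back the hand-written U-Net and discriminator.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void dims4(const NumericVector& a, int d[4], const char* what) {
  SEXP dimAttr = a.attr("dim");
  if (Rf_isNull(dimAttr)) stop("%s must be a 4-d array", what);
  IntegerVector dim(dimAttr);
  if (dim.size() != 4) stop("%s must be a 4-d array", what);
  for (int i = 0; i < 4; i++) d[i] = dim[i];
}

// Fill the im2col patch matrix P (Ho*Wo rows, k*k*Cin cols) for one sample.
// Row index = ho + Ho*wo; column index = kh + k*kw + k*k*ci, matching the
// column-major flattening of the (k, k, Cin, Cout) weight array.
static void im2col(const double* xs, int H, int W, int Cin,
                   int k, int stride, int pad, int Ho, int Wo, arma::mat& P) {
  P.zeros();
  for (int ci = 0; ci < Cin; ci++) {
    for (int kw = 0; kw < k; kw++) {
      for (int kh = 0; kh < k; kh++) {
        int col = kh + k * kw + k * k * ci;
        double* Pcol = P.colptr(col);
        for (int wo = 0; wo < Wo; wo++) {
          int wi = wo * stride + kw - pad;
          if (wi < 0 || wi >= W) continue;
          const double* xcol = xs + (size_t)H * (wi + (size_t)W * ci);
          double* Pc = Pcol + (size_t)Ho * wo;
          for (int ho = 0; ho < Ho; ho++) {
            int hi = ho * stride + kh - pad;
            if (hi < 0 || hi >= H) continue;
            Pc[ho] = xcol[hi];
          }
        }
      }
    }
  }
}

// Scatter-add of the patch-gradient matrix back onto the input gradient.
static void col2im(const arma::mat& Gp, int H, int W, int Cin,
                   int k, int stride, int pad, int Ho, int Wo, double* gxs) {
  for (int ci = 0; ci < Cin; ci++) {
    for (int kw = 0; kw < k; kw++) {
      for (int kh = 0; kh < k; kh++) {
        int col = kh + k * kw + k * k * ci;
        const double* Gcol = Gp.colptr(col);
        for (int wo = 0; wo < Wo; wo++) {
          int wi = wo * stride + kw - pad;
          if (wi < 0 || wi >= W) continue;
          double* gxcol = gxs + (size_t)H * (wi + (size_t)W * ci);
          const double* Gc = Gcol + (size_t)Ho * wo;
          for (int ho = 0; ho < Ho; ho++) {
            int hi = ho * stride + kh - pad;
            if (hi < 0 || hi >= H) continue;
            gxcol[hi] += Gc[ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  int dx[4], dw[4];
  dims4(x, dx, "x"); dims4(w, dw, "w");
  int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  int k = dw[0], Cout = dw[3];
  if (dw[1] != k) stop("kernel must be square");
  if (dw[2] != Cin) stop("input channel mismatch");
  if (b.size() != Cout) stop("bias length mismatch");
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");

  arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  NumericVector out((R_xlen_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat P(Ho * Wo, k * k * Cin);
  for (int n = 0; n < N; n++) {
    const double* xs = x.begin() + (size_t)H * W * Cin * n;
    im2col(xs, H, W, Cin, k, stride, pad, Ho, Wo, P);
    arma::mat Y = P * Wm;
    double* os = out.begin() + (size_t)Ho * Wo * Cout * n;
    for (int co = 0; co < Cout; co++) {
      const double* yc = Y.colptr(co);
      double* oc = os + (size_t)Ho * Wo * co;
      double bc = b[co];
      for (int i = 0; i < Ho * Wo; i++) oc[i] = yc[i] + bc;
    }
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int stride, int pad) {
  int dx[4], dw[4], dg[4];
  dims4(x, dx, "x"); dims4(w, dw, "w"); dims4(gy, dg, "gy");
  int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  int k = dw[0], Cout = dw[3];
  int Ho = dg[0], Wo = dg[1];
  if (dg[2] != Cout || dg[3] != N) stop("gradient shape mismatch");

  arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  NumericVector gx((R_xlen_t)H * W * Cin * N);
  gx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  NumericVector gw((R_xlen_t)k * k * Cin * Cout);
  gw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  NumericVector gb(Cout);
  arma::mat GW(gw.begin(), k * k * Cin, Cout, false, true);

  arma::mat P(Ho * Wo, k * k * Cin);
  for (int n = 0; n < N; n++) {
    const double* xs = x.begin() + (size_t)H * W * Cin * n;
    double* gxs = gx.begin() + (size_t)H * W * Cin * n;
    arma::mat Gy(const_cast<double*>(gy.begin()) + (size_t)Ho * Wo * Cout * n,
                 Ho * Wo, Cout, false, true);
    im2col(xs, H, W, Cin, k, stride, pad, Ho, Wo, P);
    GW += P.t() * Gy;
    for (int co = 0; co < Cout; co++) gb[co] += arma::accu(Gy.col(co));
    arma::mat Gp = Gy * Wm.t();
    col2im(Gp, H, W, Cin, k, stride, pad, Ho, Wo, gxs);
  }
  return List::create(Named("gx") = gx, Named("gw") = gw, Named("gb") = gb);
}
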