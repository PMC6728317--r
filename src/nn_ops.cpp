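// Minimal convolutional primitives for the GAN models: 2-D convolution
// forward/backward via im2col + GEMM, and 2x2 max pooling.  Tensors are R
// arrays with dim (H, W, C, N) in column-major order; convolution weights
// have dim (kh, kw, Cin, Cout).  Everything is double precision and
// single-threaded, so results are bit-reproducible.
#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::depends(RcppArmadillo)]]

static inline int out_size(int in, int k, int pad, int stride, int dil) {
  return (in + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// Fill the im2col matrix (K x P) for one sample; x points at that sample's
// (H, W, C) block.  Row order matches the column-major flattening of the
// first three weight dims (kh fastest, then kw, then Cin).
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int ph, int pw, int stride, int dil,
                   int Ho, int Wo, arma::mat& M) {
  M.zeros();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        for (int oj = 0; oj < Wo; ++oj) {
          const int jj = oj * stride - pw + kj * dil;
          if (jj < 0 || jj >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int ii = oi * stride - ph + ki * dil;
            if (ii < 0 || ii >= H) continue;
            M(r, oi + Ho * oj) = x[ii + H * (jj + W * c)];
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& M, double* gx, int H, int W, int C,
                       int kh, int kw, int ph, int pw, int stride, int dil,
                       int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        for (int oj = 0; oj < Wo; ++oj) {
          const int jj = oj * stride - pw + kj * dil;
          if (jj < 0 || jj >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int ii = oi * stride - ph + ki * dil;
            if (ii < 0 || ii >= H) continue;
            gx[ii + H * (jj + W * c)] += M(r, oi + Ho * oj);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(const NumericVector& x, const NumericVector& w,
                             const NumericVector& b, int stride, int ph,
                             int pw, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch");
  const int Ho = out_size(H, kh, ph, stride, dil);
  const int Wo = out_size(W, kw, pw, stride, dil);
  if (Ho < 1 || Wo < 1) stop("empty convolution output");
  const int K = kh * kw * C, P = Ho * Wo;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat M(K, P);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (R_xlen_t)n * H * W * C, H, W, C, kh, kw, ph, pw,
           stride, dil, Ho, Wo, M);
    arma::mat Y = M.t() * Wm;  // P x Cout
    double* yp = y.begin() + (R_xlen_t)n * P * Cout;
    for (int o = 0; o < Cout; ++o)
      for (int p = 0; p < P; ++p) yp[p + P * o] = Y(p, o) + b[o];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const NumericVector& x, const NumericVector& w,
                    const NumericVector& gy, int stride, int ph, int pw,
                    int dil, bool need_gx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = gd[0], Wo = gd[1];
  const int K = kh * kw * C, P = Ho * Wo;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector gw(K * Cout), gb(Cout);
  gw.attr("dim") = wd;
  NumericVector gx(need_gx ? x.size() : 0);
  if (need_gx) gx.attr("dim") = xd;
  arma::mat GW(gw.begin(), K, Cout, false, true);
  arma::mat M(K, P);
  for (int n = 0; n < N; ++n) {
    arma::mat G(const_cast<double*>(gy.begin()) + (R_xlen_t)n * P * Cout, P,
                Cout, false, true);
    im2col(x.begin() + (R_xlen_t)n * H * W * C, H, W, C, kh, kw, ph, pw,
           stride, dil, Ho, Wo, M);
    GW += M * G;
    for (int o = 0; o < Cout; ++o) gb[o] += arma::accu(G.col(o));
    if (need_gx) {
      arma::mat GM = Wm * G.t();  // K x P
      col2im_add(GM, gx.begin() + (R_xlen_t)n * H * W * C, H, W, C, kh, kw,
                 ph, pw, stride, dil, Ho, Wo);
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(const NumericVector& x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(Ho * Wo * C * N);
  IntegerVector idx(Ho * Wo * C * N);  // linear index into x of each max
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  R_xlen_t q = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      for (int oj = 0; oj < Wo; ++oj) {
        for (int oi = 0; oi < Ho; ++oi) {
          double best = -INFINITY;
          R_xlen_t bi = 0;
          for (int dj = 0; dj < 2; ++dj) {
            for (int di = 0; di < 2; ++di) {
              const R_xlen_t li = base + (2 * oi + di) + (R_xlen_t)H * (2 * oj + dj);
              if (x[li] > best) { best = x[li]; bi = li; }
            }
          }
          y[q] = best;
          idx[q] = (int)bi;
          ++q;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(const IntegerVector& idx,
                               const NumericVector& gy,
                               const IntegerVector& xdim) {
  R_xlen_t nx = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(nx);
  gx.attr("dim") = xdim;
  for (R_xlen_t q = 0; q < gy.size(); ++q) gx[idx[q]] += gy[q];
  return gx;
}
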