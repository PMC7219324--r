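// 3D convolution / pooling kernels for the dual-pathway network.
// Tensor layout throughout: column-major array with dims (C, T, H, W, N),
// i.e. channel fastest. Convolution weights arrive flattened as a
// Cout x (Cin*kt*kh*kw) matrix whose column order matches im2col row order
// (channel fastest, then dt, dh, dw) -- identical to flattening an R array
// of dim c(Cout, Cin, kt, kh, kw).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using Rcpp::IntegerVector;
using Rcpp::NumericVector;
using Rcpp::NumericMatrix;
using Rcpp::List;

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

static void im2col(const double* x, int C, int T, int H, int W,
                   int kt, int kh, int kw, int st, int sh, int sw,
                   int pt, int ph, int pw, int To, int Ho, int Wo,
                   arma::mat& col) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int to = 0; to < To; ++to) {
        const int p = to + To * (ho + (long)Ho * wo);
        double* cp = col.colptr(p);
        for (int dw = 0; dw < kw; ++dw) {
          const int wi = wo * sw - pw + dw;
          for (int dh = 0; dh < kh; ++dh) {
            const int hi = ho * sh - ph + dh;
            for (int dt = 0; dt < kt; ++dt) {
              const int ti = to * st - pt + dt;
              const long k = (long)C * (dt + (long)kt * (dh + (long)kh * dw));
              if (ti < 0 || ti >= T || hi < 0 || hi >= H || wi < 0 || wi >= W) {
                for (int c = 0; c < C; ++c) cp[k + c] = 0.0;
              } else {
                const double* xp = x + (long)C * (ti + (long)T * (hi + (long)H * wi));
                for (int c = 0; c < C; ++c) cp[k + c] = xp[c];
              }
            }
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& col, double* dx, int C, int T, int H, int W,
                       int kt, int kh, int kw, int st, int sh, int sw,
                       int pt, int ph, int pw, int To, int Ho, int Wo) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int to = 0; to < To; ++to) {
        const int p = to + To * (ho + (long)Ho * wo);
        const double* cp = col.colptr(p);
        for (int dw = 0; dw < kw; ++dw) {
          const int wi = wo * sw - pw + dw;
          if (wi < 0 || wi >= W) continue;
          for (int dh = 0; dh < kh; ++dh) {
            const int hi = ho * sh - ph + dh;
            if (hi < 0 || hi >= H) continue;
            for (int dt = 0; dt < kt; ++dt) {
              const int ti = to * st - pt + dt;
              if (ti < 0 || ti >= T) continue;
              const long k = (long)C * (dt + (long)kt * (dh + (long)kh * dw));
              double* xp = dx + (long)C * (ti + (long)T * (hi + (long)H * wi));
              for (int c = 0; c < C; ++c) xp[c] += cp[k + c];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xdim,
                             NumericMatrix wmat, IntegerVector kdim,
                             IntegerVector stride, IntegerVector pad) {
  const int C = xdim[0], T = xdim[1], H = xdim[2], W = xdim[3], N = xdim[4];
  const int kt = kdim[0], kh = kdim[1], kw = kdim[2];
  const int st = stride[0], sh = stride[1], sw = stride[2];
  const int pt = pad[0], ph = pad[1], pw = pad[2];
  const int To = out_size(T, kt, st, pt), Ho = out_size(H, kh, sh, ph),
            Wo = out_size(W, kw, sw, pw);
  const int Cout = wmat.nrow();
  const long K = (long)C * kt * kh * kw, P = (long)To * Ho * Wo;
  if ((long)wmat.ncol() != K) Rcpp::stop("weight/kernel shape mismatch");

  NumericVector y((long)Cout * P * N);
  arma::mat Wm(wmat.begin(), Cout, K, false, true);
  arma::mat col(K, P);
  const long xstride = (long)C * T * H * W, ystride = (long)Cout * P;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * xstride, C, T, H, W, kt, kh, kw, st, sh, sw,
           pt, ph, pw, To, Ho, Wo, col);
    arma::mat Y(y.begin() + n * ystride, Cout, P, false, true);
    Y = Wm * col;
  }
  y.attr("dim") = IntegerVector::create(Cout, To, Ho, Wo, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector xdim,
                    NumericMatrix wmat, IntegerVector kdim,
                    IntegerVector stride, IntegerVector pad,
                    NumericVector dy, bool need_dx) {
  const int C = xdim[0], T = xdim[1], H = xdim[2], W = xdim[3], N = xdim[4];
  const int kt = kdim[0], kh = kdim[1], kw = kdim[2];
  const int st = stride[0], sh = stride[1], sw = stride[2];
  const int pt = pad[0], ph = pad[1], pw = pad[2];
  const int To = out_size(T, kt, st, pt), Ho = out_size(H, kh, sh, ph),
            Wo = out_size(W, kw, sw, pw);
  const int Cout = wmat.nrow();
  const long K = (long)C * kt * kh * kw, P = (long)To * Ho * Wo;

  NumericVector dx(need_dx ? x.size() : 1);
  NumericMatrix dw(Cout, K);
  arma::mat Wm(wmat.begin(), Cout, K, false, true);
  arma::mat dWm(dw.begin(), Cout, K, false, true);
  arma::mat col(K, P);
  const long xstride = (long)C * T * H * W, ystride = (long)Cout * P;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * xstride, C, T, H, W, kt, kh, kw, st, sh, sw,
           pt, ph, pw, To, Ho, Wo, col);
    const arma::mat dY(const_cast<double*>(dy.begin()) + n * ystride, Cout, P, false, true);
    dWm += dY * col.t();
    if (need_dx) {
      arma::mat dcol = Wm.t() * dY;
      col2im_add(dcol, dx.begin() + n * xstride, C, T, H, W, kt, kh, kw,
                 st, sh, sw, pt, ph, pw, To, Ho, Wo);
    }
  }
  if (need_dx) dx.attr("dim") = xdim;
  return List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw);
}

// [[Rcpp::export]]
List cpp_maxpool3d_fwd(NumericVector x, IntegerVector xdim,
                       IntegerVector kdim, IntegerVector stride,
                       IntegerVector pad) {
  const int C = xdim[0], T = xdim[1], H = xdim[2], W = xdim[3], N = xdim[4];
  const int kt = kdim[0], kh = kdim[1], kw = kdim[2];
  const int st = stride[0], sh = stride[1], sw = stride[2];
  const int pt = pad[0], ph = pad[1], pw = pad[2];
  const int To = out_size(T, kt, st, pt), Ho = out_size(H, kh, sh, ph),
            Wo = out_size(W, kw, sw, pw);
  const long ylen = (long)C * To * Ho * Wo * N;
  NumericVector y(ylen);
  IntegerVector amax(ylen);  // 1-based linear index into x
  const long xstride = (long)C * T * H * W;

  long q = 0;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + n * xstride;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int to = 0; to < To; ++to)
          for (int c = 0; c < C; ++c) {
            double best = -std::numeric_limits<double>::infinity();
            long besti = -1;
            for (int dw = 0; dw < kw; ++dw) {
              const int wi = wo * sw - pw + dw;
              if (wi < 0 || wi >= W) continue;
              for (int dh = 0; dh < kh; ++dh) {
                const int hi = ho * sh - ph + dh;
                if (hi < 0 || hi >= H) continue;
                for (int dt = 0; dt < kt; ++dt) {
                  const int ti = to * st - pt + dt;
                  if (ti < 0 || ti >= T) continue;
                  const long ix = c + (long)C * (ti + (long)T * (hi + (long)H * wi));
                  if (xn[ix] > best) { best = xn[ix]; besti = ix; }
                }
              }
            }
            // y is filled in (c fastest, then to, ho, wo) order per sample,
            // but tensor layout needs c + C*(to + To*(ho + Ho*wo)); compute
            // the target position explicitly.
            const long yo = c + (long)C * (to + (long)To * (ho + (long)Ho * wo))
                            + n * (long)C * To * Ho * Wo;
            y[yo] = best;
            amax[yo] = (int)(besti + n * xstride) + 1;
            ++q;
          }
  }
  (void)q;
  y.attr("dim") = IntegerVector::create(C, To, Ho, Wo, N);
  return List::create(Rcpp::Named("y") = y, Rcpp::Named("argmax") = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bwd(NumericVector dy, IntegerVector amax, int xlen) {
  NumericVector dx(xlen);
  const long n = dy.size();
  for (long i = 0; i < n; ++i) dx[amax[i] - 1] += dy[i];
  return dx;
}
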