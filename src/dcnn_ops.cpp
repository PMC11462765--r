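// Inner loops of the two-block convolutional classifier: im2col-based 2D
// convolution (forward and backward) and non-overlapping max pooling.
// Layouts follow R column-major arrays: images (h, w, c, n), kernels
// (k, k, c_in, f). The kernel array flattens directly into the im2col
// weight matrix (k*k*c_in rows, f columns).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void im2col(const double* x, int h, int w, int cin,
                          int k, int stride, int pad, int ho, int wo,
                          arma::mat& cols) {
  for (int c = 0; c < cin; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int row = ki + k * (kj + k * c);
        for (int oj = 0; oj < wo; ++oj) {
          const int in_j = oj * stride + kj - pad;
          for (int oi = 0; oi < ho; ++oi) {
            const int in_i = oi * stride + ki - pad;
            double v = 0.0;
            if (in_i >= 0 && in_i < h && in_j >= 0 && in_j < w)
              v = x[in_i + h * (in_j + w * c)];
            cols(row, oi + ho * oj) = v;
          }
        }
      }
    }
  }
}

static inline void col2im_add(const arma::mat& cols, int h, int w, int cin,
                              int k, int stride, int pad, int ho, int wo,
                              double* dx) {
  for (int c = 0; c < cin; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int row = ki + k * (kj + k * c);
        for (int oj = 0; oj < wo; ++oj) {
          const int in_j = oj * stride + kj - pad;
          if (in_j < 0 || in_j >= w) continue;
          for (int oi = 0; oi < ho; ++oi) {
            const int in_i = oi * stride + ki - pad;
            if (in_i < 0 || in_i >= h) continue;
            dx[in_i + h * (in_j + w * c)] += cols(row, oi + ho * oj);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv_fwd(NumericVector x, NumericVector wt, NumericVector b,
                       int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = wt.attr("dim");
  const int h = xd[0], w = xd[1], cin = xd[2], n = xd[3];
  const int k = wd[0], f = wd[3];
  const int ho = (h + 2 * pad - k) / stride + 1;
  const int wo = (w + 2 * pad - k) / stride + 1;
  const int kkc = k * k * cin, howo = ho * wo;

  const arma::mat W(const_cast<double*>(wt.begin()), kkc, f, false, true);
  NumericVector y(static_cast<R_xlen_t>(howo) * f * n);
  y.attr("dim") = IntegerVector::create(ho, wo, f, n);
  arma::mat cols(kkc, howo);

  for (int s = 0; s < n; ++s) {
    im2col(x.begin() + static_cast<R_xlen_t>(s) * h * w * cin,
           h, w, cin, k, stride, pad, ho, wo, cols);
    arma::mat Y(y.begin() + static_cast<R_xlen_t>(s) * howo * f, howo, f, false, true);
    Y = cols.t() * W;  // (howo, f), written in place
    for (int fi = 0; fi < f; ++fi) Y.col(fi) += b[fi];
  }
  return y;
}

// [[Rcpp::export]]
List conv_bwd(NumericVector x, NumericVector wt, NumericVector dy,
              int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = wt.attr("dim"), yd = dy.attr("dim");
  const int h = xd[0], w = xd[1], cin = xd[2], n = xd[3];
  const int k = wd[0], f = wd[3];
  const int ho = yd[0], wo = yd[1];
  const int kkc = k * k * cin, howo = ho * wo;

  const arma::mat W(const_cast<double*>(wt.begin()), kkc, f, false, true);
  NumericVector dx(x.size()); dx.attr("dim") = xd;
  NumericVector dw(wt.size()); dw.attr("dim") = wd;
  NumericVector db(f);
  arma::mat dW(dw.begin(), kkc, f, false, true);
  arma::mat cols(kkc, howo);

  for (int s = 0; s < n; ++s) {
    const arma::mat dY(const_cast<double*>(dy.begin()) + static_cast<R_xlen_t>(s) * howo * f,
                       howo, f, false, true);  // (howo, f) view
    im2col(x.begin() + static_cast<R_xlen_t>(s) * h * w * cin,
           h, w, cin, k, stride, pad, ho, wo, cols);
    dW += cols * dY;
    for (int fi = 0; fi < f; ++fi) db[fi] += arma::accu(dY.col(fi));
    arma::mat dcols = W * dY.t();  // (kkc, howo)
    col2im_add(dcols, h, w, cin, k, stride, pad, ho, wo,
               dx.begin() + static_cast<R_xlen_t>(s) * h * w * cin);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List pool_fwd(NumericVector x, int p) {
  IntegerVector xd = x.attr("dim");
  const int h = xd[0], w = xd[1], c = xd[2], n = xd[3];
  const int ho = h / p, wo = w / p;
  NumericVector y(static_cast<R_xlen_t>(ho) * wo * c * n);
  IntegerVector arg(y.size());
  y.attr("dim") = IntegerVector::create(ho, wo, c, n);
  arg.attr("dim") = IntegerVector::create(ho, wo, c, n);

  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = arg.begin();
  for (int s = 0; s < n; ++s) {
    const R_xlen_t xin = static_cast<R_xlen_t>(s) * h * w * c;
    const R_xlen_t yin = static_cast<R_xlen_t>(s) * ho * wo * c;
    for (int ci = 0; ci < c; ++ci) {
      for (int oj = 0; oj < wo; ++oj) {
        for (int oi = 0; oi < ho; ++oi) {
          double best = -1e300; int bidx = 0;
          for (int kj = 0; kj < p; ++kj) {
            for (int ki = 0; ki < p; ++ki) {
              const int ii = oi * p + ki, jj = oj * p + kj;
              const int idx = ii + h * (jj + w * ci);
              const double v = xp[xin + idx];
              if (v > best) { best = v; bidx = idx; }
            }
          }
          const R_xlen_t oidx = yin + oi + ho * (oj + wo * ci);
          yp[oidx] = best;
          ap[oidx] = bidx;  // offset within sample
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector pool_bwd(IntegerVector arg, NumericVector dy, IntegerVector xdim) {
  IntegerVector yd = dy.attr("dim");
  const int ho = yd[0], wo = yd[1], c = yd[2], n = yd[3];
  const R_xlen_t per = static_cast<R_xlen_t>(xdim[0]) * xdim[1] * xdim[2];
  NumericVector dx(per * n);
  dx.attr("dim") = xdim;
  const R_xlen_t oper = static_cast<R_xlen_t>(ho) * wo * c;
  const int* ap = arg.begin();
  const double* dp = dy.begin();
  double* xp = dx.begin();
  for (int s = 0; s < n; ++s)
    for (R_xlen_t q = 0; q < oper; ++q)
      xp[per * s + ap[oper * s + q]] += dp[oper * s + q];
  return dx;
}

// Fused batch-norm affine transform + ReLU: y = max(z * scale[c] + shift[c], 0)
// [[Rcpp::export]]
NumericVector bn_fwd_relu(NumericVector z, NumericVector scale, NumericVector shift) {
  IntegerVector zd = z.attr("dim");
  const int hw = zd[0] * zd[1], f = zd[2], n = zd[3];
  NumericVector y(z.size());
  y.attr("dim") = zd;
  const double* zp = z.begin();
  double* yp = y.begin();
  for (int s = 0; s < n; ++s) {
    for (int c = 0; c < f; ++c) {
      const R_xlen_t off = static_cast<R_xlen_t>(hw) * (c + static_cast<R_xlen_t>(f) * s);
      const double sc = scale[c], sh = shift[c];
      for (int q = 0; q < hw; ++q) {
        const double v = zp[off + q] * sc + sh;
        yp[off + q] = v > 0 ? v : 0;
      }
    }
  }
  return y;
}

// Batch-norm backward (batch statistics), with the incoming gradient dy
// already masked by the ReLU. Returns dz plus the gamma/beta gradients.
// [[Rcpp::export]]
List bn_bwd(NumericVector dy, NumericVector z, NumericVector mu,
            NumericVector invsd, NumericVector gamma) {
  IntegerVector zd = z.attr("dim");
  const int hw = zd[0] * zd[1], f = zd[2], n = zd[3];
  const double m = static_cast<double>(hw) * n;
  NumericVector dz(z.size()), dgamma(f), dbeta(f);
  dz.attr("dim") = zd;
  const double* zp = z.begin();
  const double* dyp = dy.begin();
  double* dzp = dz.begin();
  for (int c = 0; c < f; ++c) {
    double sb = 0.0, sg = 0.0;
    const double muc = mu[c], isd = invsd[c];
    for (int s = 0; s < n; ++s) {
      const R_xlen_t off = static_cast<R_xlen_t>(hw) * (c + static_cast<R_xlen_t>(f) * s);
      for (int q = 0; q < hw; ++q) {
        const double zh = (zp[off + q] - muc) * isd;
        sb += dyp[off + q];
        sg += dyp[off + q] * zh;
      }
    }
    dbeta[c] = sb; dgamma[c] = sg;
    const double k = gamma[c] * isd, bm = sb / m, gm = sg / m;
    for (int s = 0; s < n; ++s) {
      const R_xlen_t off = static_cast<R_xlen_t>(hw) * (c + static_cast<R_xlen_t>(f) * s);
      for (int q = 0; q < hw; ++q) {
        const double zh = (zp[off + q] - muc) * isd;
        dzp[off + q] = (dyp[off + q] - bm - zh * gm) * k;
      }
    }
  }
  return List::create(_["dz"] = dz, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// ReLU mask multiply: out = dy * (act > 0), reusing no R temporaries
// [[Rcpp::export]]
NumericVector relu_mask_mul(NumericVector dy, NumericVector act) {
  NumericVector out(dy.size());
  out.attr("dim") = dy.attr("dim");
  const double* dp = dy.begin();
  const double* ap = act.begin();
  double* op = out.begin();
  const R_xlen_t nn = dy.size();
  for (R_xlen_t i = 0; i < nn; ++i) op[i] = ap[i] > 0 ? dp[i] : 0.0;
  return out;
}
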