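// Low-level 2-D correlation ("conv") forward/backward used by the GAN.
// Layout: feature maps are H x W x C cubes; weights are (k, k, Cin, Cout)
// arrays; 'same' zero padding, stride 1. Implemented as im2col + GEMM so
// the heavy lifting happens inside BLAS; the backward pass is the exact
// adjoint of the forward pass.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// column block index for kernel offset (u, v) and input channel ci
static inline int colblk(int u, int v, int ci, int k) {
  return u + k * (v + k * ci);
}

static arma::mat im2col(const arma::cube &x, int k) {
  int H = x.n_rows, W = x.n_cols, cin = x.n_slices, p = (k - 1) / 2;
  arma::mat col(H * W, k * k * cin, arma::fill::zeros);
  for (int ci = 0; ci < cin; ++ci) {
    const arma::mat &xs = x.slice(ci);
    for (int v = 0; v < k; ++v) {
      int dc = v - p;
      int c0 = std::max(0, -dc), c1 = std::min(W - 1, W - 1 - dc);
      for (int u = 0; u < k; ++u) {
        int dr = u - p;
        int r0 = std::max(0, -dr), r1 = std::min(H - 1, H - 1 - dr);
        double *dst = col.colptr(colblk(u, v, ci, k));
        for (int c = c0; c <= c1; ++c) {
          const double *src = xs.colptr(c + dc) + (r0 + dr);
          std::copy(src, src + (r1 - r0 + 1), dst + c * H + r0);
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube &x, const NumericVector &w,
                      const NumericVector &b) {
  IntegerVector wd = w.attr("dim");
  int k = wd[0], cin = wd[2], cout = wd[3];
  int H = x.n_rows, W = x.n_cols;
  arma::mat wm(const_cast<double *>(&w[0]), k * k * cin, cout, false, true);
  arma::mat y = im2col(x, k) * wm;
  arma::cube out(H, W, cout);
  for (int co = 0; co < cout; ++co) {
    arma::mat m(y.colptr(co), H, W, false, true);
    out.slice(co) = m + b[co];
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd(const arma::cube &x, const NumericVector &w,
                const arma::cube &dy) {
  IntegerVector wd = w.attr("dim");
  int k = wd[0], cin = wd[2], cout = wd[3];
  int H = x.n_rows, W = x.n_cols, p = (k - 1) / 2;
  arma::mat wm(const_cast<double *>(&w[0]), k * k * cin, cout, false, true);
  arma::mat dym(const_cast<double *>(dy.memptr()), H * W, cout, false, true);

  NumericVector dwv(w.size());
  dwv.attr("dim") = wd;
  arma::mat dwm(&dwv[0], k * k * cin, cout, false, true);
  dwm = im2col(x, k).t() * dym;

  NumericVector db(cout);
  for (int co = 0; co < cout; ++co) db[co] = arma::accu(dy.slice(co));

  // dx: scatter-add the column gradient back (adjoint of im2col)
  arma::mat dcol = dym * wm.t();
  arma::cube dx(H, W, cin, arma::fill::zeros);
  for (int ci = 0; ci < cin; ++ci) {
    arma::mat &dxs = dx.slice(ci);
    for (int v = 0; v < k; ++v) {
      int dc = v - p;
      int c0 = std::max(0, -dc), c1 = std::min(W - 1, W - 1 - dc);
      for (int u = 0; u < k; ++u) {
        int dr = u - p;
        int r0 = std::max(0, -dr), r1 = std::min(H - 1, H - 1 - dr);
        const double *src = dcol.colptr(colblk(u, v, ci, k));
        for (int c = c0; c <= c1; ++c) {
          double *dst = dxs.colptr(c + dc) + (r0 + dr);
          const double *s = src + c * H + r0;
          for (int r = 0; r <= r1 - r0; ++r) dst[r] += s[r];
        }
      }
    }
  }
  return List::create(Named("dx") = dx, Named("dw") = dwv, Named("db") = db);
}
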