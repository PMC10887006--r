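// Hot numerical kernels: 3x3 same-padding convolution (im2col + GEMM) and
// per-feature-map normalization. Shapes follow the R side: feature maps are
// H x W x C cubes; conv weights are (9*C_in) x C_out matrices whose rows are
// ordered channel-fast within kernel tap (tap index k = dy + 3*dx over the
// zero-padded input).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col3(const arma::cube& x) {
  const arma::uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat M(H * W, 9 * C);
  for (arma::uword c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    for (arma::uword k = 0; k < 9; ++k) {
      const int dy = static_cast<int>(k % 3) - 1;
      const int dx = static_cast<int>(k / 3) - 1;
      double* out = M.colptr(k * C + c);
      for (arma::uword j = 0; j < W; ++j) {
        const int js = static_cast<int>(j) + dx;
        double* col = out + j * H;
        if (js < 0 || js >= static_cast<int>(W)) {
          std::fill(col, col + H, 0.0);
          continue;
        }
        const double* src = xc.colptr(js);
        const int lo = std::max(0, -dy);
        const int hi = std::min(static_cast<int>(H),
                                static_cast<int>(H) - dy);
        if (lo > 0) std::fill(col, col + lo, 0.0);
        if (hi < static_cast<int>(H)) std::fill(col + hi, col + H, 0.0);
        for (int i = lo; i < hi; ++i) col[i] = src[i + dy];
      }
    }
  }
  return M;
}

// [[Rcpp::export(name = ".conv3_fwd_cpp")]]
arma::cube conv3_fwd_cpp(const arma::cube& x, const arma::mat& W,
                         const arma::vec& b) {
  const arma::uword H = x.n_rows, Wd = x.n_cols;
  arma::mat Y = im2col3(x) * W;
  Y.each_row() += b.t();
  arma::cube out(Y.memptr(), H, Wd, W.n_cols);
  return out;
}

// [[Rcpp::export(name = ".conv3_bwd_cpp")]]
List conv3_bwd_cpp(const arma::cube& x, const arma::mat& W,
                   const arma::cube& dout) {
  const arma::uword H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const arma::uword Cout = W.n_cols;
  arma::mat dmat(const_cast<double*>(dout.memptr()), H * Wd, Cout, false);
  arma::mat M = im2col3(x);
  arma::mat dW = M.t() * dmat;
  arma::vec db = arma::sum(dmat, 0).t();
  arma::mat dM = dmat * W.t();
  // col2im: scatter patch gradients back onto the (unpadded) image
  arma::cube dx(H, Wd, C, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c) {
    arma::mat& dxc = dx.slice(c);
    for (arma::uword k = 0; k < 9; ++k) {
      const int dy = static_cast<int>(k % 3) - 1;
      const int dx_ = static_cast<int>(k / 3) - 1;
      const double* src = dM.colptr(k * C + c);
      for (arma::uword j = 0; j < Wd; ++j) {
        const int js = static_cast<int>(j) + dx_;
        if (js < 0 || js >= static_cast<int>(Wd)) continue;
        double* dst = dxc.colptr(js);
        const double* scol = src + j * H;
        const int lo = std::max(0, -dy);
        const int hi = std::min(static_cast<int>(H),
                                static_cast<int>(H) - dy);
        for (int i = lo; i < hi; ++i) dst[i + dy] += scol[i];
      }
    }
  }
  return List::create(Named("dx") = dx, Named("dW") = dW, Named("db") = db);
}

// [[Rcpp::export(name = ".norm_fwd_cpp")]]
List norm_fwd_cpp(const arma::cube& x, const arma::vec& gamma,
                  const arma::vec& beta, const double eps) {
  const arma::uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const double n = static_cast<double>(H * W);
  arma::cube y(H, W, C);
  arma::vec mu(C), sd(C);
  for (arma::uword c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    const double m = arma::accu(xc) / n;
    double v = arma::accu(arma::square(xc)) / n - m * m;
    if (v < 0) v = 0;
    const double s = std::sqrt(v + eps);
    mu[c] = m;
    sd[c] = s;
    y.slice(c) = (gamma[c] / s) * xc + (beta[c] - m * gamma[c] / s);
  }
  return List::create(Named("out") = y, Named("mu") = mu, Named("sd") = sd);
}

// [[Rcpp::export(name = ".norm_bwd_cpp")]]
List norm_bwd_cpp(const arma::cube& x, const arma::cube& dout,
                  const arma::vec& gamma, const arma::vec& mu,
                  const arma::vec& sd) {
  const arma::uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const double n = static_cast<double>(H * W);
  arma::cube dx(H, W, C);
  arma::vec dgamma(C), dbeta(C);
  for (arma::uword c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    const arma::mat& dc = dout.slice(c);
    const double sxd = arma::accu(dc % xc);
    const double s1 = arma::accu(dc);
    dbeta[c] = s1;
    dgamma[c] = (sxd - mu[c] * s1) / sd[c];
    const double m1 = gamma[c] * s1 / n;
    const double m2 = gamma[c] * (sxd - mu[c] * s1) / (sd[c] * n);
    dx.slice(c) = (gamma[c] / sd[c]) * dc - (m2 / (sd[c] * sd[c])) * xc +
      (mu[c] * m2 / sd[c] - m1) / sd[c];
  }
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}
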