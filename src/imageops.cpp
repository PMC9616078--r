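// Small image kernels for preprocessing hot paths.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Per-channel affine map a[c] * x + b[c], clipped to [0, 255] and rounded.
// [[Rcpp::export]]
arma::cube cpp_affine_clip255(const arma::cube &x, const arma::vec &a,
                              const arma::vec &b) {
  arma::cube out(x.n_rows, x.n_cols, x.n_slices);
  const size_t npix = static_cast<size_t>(x.n_rows) * x.n_cols;
  for (arma::uword c = 0; c < x.n_slices; ++c) {
    const double *xp = x.memptr() + c * npix;
    double *op = out.memptr() + c * npix;
    const double ac = a(c), bc = b(c);
    for (size_t i = 0; i < npix; ++i) {
      double v = ac * xp[i] + bc;
      if (v < 0) v = 0;
      else if (v > 255) v = 255;
      op[i] = std::nearbyint(v);
    }
  }
  return out;
}

// HSV-style saturation (max-min)/max per pixel of an RGB cube (0 where the
// maximum channel is 0).
// [[Rcpp::export]]
arma::mat cpp_saturation(const arma::cube &x) {
  const size_t npix = static_cast<size_t>(x.n_rows) * x.n_cols;
  arma::mat out(x.n_rows, x.n_cols);
  const double *r = x.memptr(), *g = r + npix, *b = g + npix;
  double *op = out.memptr();
  for (size_t i = 0; i < npix; ++i) {
    double mx = std::max(r[i], std::max(g[i], b[i]));
    double mn = std::min(r[i], std::min(g[i], b[i]));
    op[i] = mx > 0 ? (mx - mn) / mx : 0.0;
  }
  return out;
}
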