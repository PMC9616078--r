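// Minimal 2-D convolution / pooling / upsampling kernels for the patch
// segmenter. Tensors are arma::cube in H x W x C layout (matches an R array
// with dim = c(H, W, C)). Convolutions are k x k, stride 1, zero-padded to
// "same" size; weights are stored as a (k*k*Cin) x Cout matrix so the
// forward pass is a single GEMM on the im2col matrix.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Build the im2col matrix: rows index pixels (column-major over H x W),
// columns index (offset, channel) pairs in the order used by conv weights:
// col = c * k * k + dy * k + dx   (dy, dx in 0..k-1). The inner run over
// rows is contiguous in both source and destination, so it is a memcpy.
static arma::mat im2col(const arma::cube &x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = (k - 1) / 2;
  const size_t npix = static_cast<size_t>(H) * W;
  arma::mat out(npix, static_cast<size_t>(k) * k * C, arma::fill::zeros);
  const double *xp = x.memptr();
  double *op = out.memptr();
  for (int c = 0; c < C; ++c) {
    const double *xc = xp + static_cast<size_t>(c) * npix;
    for (int dy = 0; dy < k; ++dy) {
      for (int dx = 0; dx < k; ++dx) {
        const int col = c * k * k + dy * k + dx;
        const int oy = dy - pad, ox = dx - pad;
        const int i0 = std::max(0, -oy), i1 = std::min(H, H - oy);
        if (i1 <= i0) continue;
        double *oc = op + static_cast<size_t>(col) * npix;
        for (int j = std::max(0, -ox); j < std::min(W, W - ox); ++j) {
          const int js = j + ox;
          std::memcpy(oc + static_cast<size_t>(j) * H + i0,
                      xc + static_cast<size_t>(js) * H + i0 + oy,
                      sizeof(double) * (i1 - i0));
        }
      }
    }
  }
  return out;
}

// Scatter-add of a column matrix back onto an image cube (adjoint of im2col).
static arma::cube col2im(const arma::mat &cols, const int H, const int W,
                         const int C, const int k) {
  const int pad = (k - 1) / 2;
  const size_t npix = static_cast<size_t>(H) * W;
  arma::cube out(H, W, C, arma::fill::zeros);
  const double *cp = cols.memptr();
  double *op = out.memptr();
  for (int c = 0; c < C; ++c) {
    double *oc = op + static_cast<size_t>(c) * npix;
    for (int dy = 0; dy < k; ++dy) {
      for (int dx = 0; dx < k; ++dx) {
        const int col = c * k * k + dy * k + dx;
        const int oy = dy - pad, ox = dx - pad;
        const int i0 = std::max(0, -oy), i1 = std::min(H, H - oy);
        if (i1 <= i0) continue;
        const double *cc = cp + static_cast<size_t>(col) * npix;
        for (int j = std::max(0, -ox); j < std::min(W, W - ox); ++j) {
          const int js = j + ox;
          const double *src = cc + static_cast<size_t>(j) * H + i0;
          double *dst = oc + static_cast<size_t>(js) * H + i0 + oy;
          for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fw(const arma::cube &x, const arma::mat &W,
                         const arma::vec &b, const int k) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int Cout = W.n_cols;
  if (static_cast<int>(W.n_rows) != k * k * static_cast<int>(x.n_slices))
    stop("conv weight shape does not match input channels/kernel");
  arma::mat cols = im2col(x, k);
  arma::mat out = cols * W;
  out.each_row() += b.t();
  arma::cube res(H, Wd, Cout);
  std::memcpy(res.memptr(), out.memptr(), sizeof(double) * out.n_elem);
  return res;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(const arma::cube &x, const arma::mat &W,
                   const arma::cube &gout, const int k) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = gout.n_slices;
  arma::mat gmat(const_cast<double *>(gout.memptr()),
                 static_cast<size_t>(H) * Wd, Cout, false, true);
  arma::mat cols = im2col(x, k);
  arma::mat gW = cols.t() * gmat;
  arma::vec gb = arma::sum(gmat, 0).t();
  arma::mat gcols = gmat * W.t();
  arma::cube gx = col2im(gcols, H, Wd, Cin, k);
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// 2x2 average pooling, stride 2 (H, W assumed even).
// [[Rcpp::export]]
arma::cube cpp_avgpool2_fw(const arma::cube &x) {
  const int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  arma::cube out(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        out(i, j, c) = 0.25 * (x(2 * i, 2 * j, c) + x(2 * i + 1, 2 * j, c) +
                               x(2 * i, 2 * j + 1, c) +
                               x(2 * i + 1, 2 * j + 1, c));
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_avgpool2_bw(const arma::cube &g) {
  const int H = g.n_rows, W = g.n_cols, C = g.n_slices;
  arma::cube out(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = 0.25 * g(i, j, c);
        out(2 * i, 2 * j, c) = v;
        out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v;
        out(2 * i + 1, 2 * j + 1, c) = v;
      }
  return out;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
arma::cube cpp_upsample2_fw(const arma::cube &x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube out(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        out(2 * i, 2 * j, c) = v;
        out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v;
        out(2 * i + 1, 2 * j + 1, c) = v;
      }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bw(const arma::cube &g) {
  const int H = g.n_rows / 2, W = g.n_cols / 2, C = g.n_slices;
  arma::cube out(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        out(i, j, c) = g(2 * i, 2 * j, c) + g(2 * i + 1, 2 * j, c) +
                       g(2 * i, 2 * j + 1, c) + g(2 * i + 1, 2 * j + 1, c);
  return out;
}
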