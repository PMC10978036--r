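#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Patch extraction and its adjoint for stride-1, zero-padded ("same")
// correlation with an odd square kernel.  Convolution itself is done in R as
// a single GEMM against these matrices, so BLAS carries the arithmetic.
//
// Layout contract (shared with the R side, see conv_forward() in R/cnn.R):
//   rows of the patch matrix index pixels in column-major order (i + j*H),
//   columns index (channel, kernel-col, kernel-row) nested as
//   ((c*k + (dj+p))*k + (di+p)) with p = (k-1)/2, all 0-based.

// [[Rcpp::export]]
arma::mat im2col_cpp(const arma::cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, p = (k - 1) / 2;
  arma::mat out(H * W, (arma::uword)k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = -p; dj <= p; ++dj) {
      for (int di = -p; di <= p; ++di) {
        const arma::uword col = ((arma::uword)c * k + (dj + p)) * k + (di + p);
        double* o = out.colptr(col);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        for (int j = j0; j < j1; ++j) {
          const double* src = x.slice_colptr(c, j + dj);
          double* dst = o + (arma::uword)j * H;
          for (int i = i0; i < i1; ++i) dst[i] = src[i + di];
        }
      }
    }
  }
  return out;
}

// Exact adjoint of im2col_cpp: scatter-add patch columns back into an image.
// [[Rcpp::export]]
arma::cube col2im_cpp(const arma::mat& cols, const int H, const int W,
                      const int C, const int k) {
  const int p = (k - 1) / 2;
  arma::cube out(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = -p; dj <= p; ++dj) {
      for (int di = -p; di <= p; ++di) {
        const arma::uword col = ((arma::uword)c * k + (dj + p)) * k + (di + p);
        const double* src0 = cols.colptr(col);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        for (int j = j0; j < j1; ++j) {
          double* dst = out.slice_colptr(c, j + dj);
          const double* src = src0 + (arma::uword)j * H;
          for (int i = i0; i < i1; ++i) dst[i + di] += src[i];
        }
      }
    }
  }
  return out;
}
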