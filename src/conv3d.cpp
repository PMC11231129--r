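#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// 3x3x3 "same" (zero-padded) 3D convolution primitives for the residual
// U-Net, implemented as im2col + GEMM so that the inner loop runs in BLAS.
//
// Layout conventions (column-major, matching R arrays):
//   x: (D1, D2, D3, Cin) flattened; y: (D1, D2, D3, Cout) flattened.
//   W: matrix (27*Cin, Cout); row index r = o + 27*cin with
//      o = (dx+1) + 3*(dy+1) + 9*(dz+1); this equals the column-major
//      flattening of an R array of dim (3, 3, 3, Cin).

static arma::mat im2col3(const double* x, int D1, int D2, int D3, int Cin) {
  const arma::uword N = (arma::uword)D1 * D2 * D3;
  arma::mat M(N, (arma::uword)27 * Cin);
  const arma::uword plane = (arma::uword)D1 * D2;
  const arma::uword volsz = plane * D3;
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (arma::uword)c * volsz;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          const int o = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
          double* col = M.colptr((arma::uword)c * 27 + o);
          for (int iz = 0; iz < D3; ++iz) {
            const int jz = iz + dz;
            const bool zin = jz >= 0 && jz < D3;
            for (int iy = 0; iy < D2; ++iy) {
              const int jy = iy + dy;
              const bool yin = zin && jy >= 0 && jy < D2;
              double* dst = col + iz * plane + (arma::uword)iy * D1;
              if (!yin) {
                std::fill(dst, dst + D1, 0.0);
                continue;
              }
              const double* src = xc + jz * plane + (arma::uword)jy * D1;
              const int lo = std::max(0, -dx), hi = std::min(D1, D1 - dx);
              for (int ix = 0; ix < lo; ++ix) dst[ix] = 0.0;
              for (int ix = lo; ix < hi; ++ix) dst[ix] = src[ix + dx];
              for (int ix = hi; ix < D1; ++ix) dst[ix] = 0.0;
            }
          }
        }
  }
  return M;
}

// scatter-add the columns of M back into an image (transpose of im2col3)
static void col2im3(const arma::mat& M, double* dx_out,
                    int D1, int D2, int D3, int Cin) {
  const arma::uword plane = (arma::uword)D1 * D2;
  const arma::uword volsz = plane * D3;
  std::fill(dx_out, dx_out + volsz * Cin, 0.0);
  for (int c = 0; c < Cin; ++c) {
    double* xc = dx_out + (arma::uword)c * volsz;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          const int o = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
          const double* col = M.colptr((arma::uword)c * 27 + o);
          for (int iz = 0; iz < D3; ++iz) {
            const int jz = iz + dz;
            if (jz < 0 || jz >= D3) continue;
            for (int iy = 0; iy < D2; ++iy) {
              const int jy = iy + dy;
              if (jy < 0 || jy >= D2) continue;
              const double* src = col + iz * plane + (arma::uword)iy * D1;
              double* dst = xc + jz * plane + (arma::uword)jy * D1;
              const int lo = std::max(0, -dx), hi = std::min(D1, D1 - dx);
              for (int ix = lo; ix < hi; ++ix) dst[ix + dx] += src[ix];
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(const NumericVector& x, const IntegerVector& dims,
                             const NumericMatrix& W, const NumericVector& b) {
  const int D1 = dims[0], D2 = dims[1], D3 = dims[2], Cin = dims[3];
  const int Cout = W.ncol();
  arma::mat M = im2col3(x.begin(), D1, D2, D3, Cin);
  const arma::mat Wm(const_cast<double*>(W.begin()), W.nrow(), W.ncol(), false);
  arma::mat Y = M * Wm;
  Y.each_row() += arma::rowvec(const_cast<double*>(b.begin()), b.size(), false);
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(D1, D2, D3, Cout);
  return out;
}

// [[Rcpp::export]]
List conv3d_bwd_cpp(const NumericVector& x, const IntegerVector& dims,
                    const NumericMatrix& W, const NumericVector& dy,
                    bool need_dx) {
  const int D1 = dims[0], D2 = dims[1], D3 = dims[2], Cin = dims[3];
  const int Cout = W.ncol();
  const arma::uword N = (arma::uword)D1 * D2 * D3;
  const arma::mat Wm(const_cast<double*>(W.begin()), W.nrow(), W.ncol(), false);
  const arma::mat dY(const_cast<double*>(dy.begin()), N, Cout, false);
  arma::mat M = im2col3(x.begin(), D1, D2, D3, Cin);
  arma::mat dW = M.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);
  NumericMatrix dWr(dW.n_rows, dW.n_cols);
  std::copy(dW.begin(), dW.end(), dWr.begin());
  NumericVector dbr(db.begin(), db.end());
  if (!need_dx)
    return List::create(_["dW"] = dWr, _["db"] = dbr);
  arma::mat dM = dY * Wm.t();
  NumericVector dxr((R_xlen_t)N * Cin);
  col2im3(dM, dxr.begin(), D1, D2, D3, Cin);
  dxr.attr("dim") = IntegerVector::create(D1, D2, D3, Cin);
  return List::create(_["dW"] = dWr, _["db"] = dbr, _["dx"] = dxr);
}
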