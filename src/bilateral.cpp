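#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Anisotropic 3D bilateral filter, shifted-offset accumulation.
//
// For each target voxel m the output is
//   sum_n W(m,n) I_n / sum_n W(m,n)
// over the truncated neighbourhood (per-axis voxel radii in `radii`)
// intersected with the volume bounds: out-of-bounds voxels are simply
// absent from both sums (border renormalisation), so every output value
// is a convex combination of in-bounds input values.
//
// The spatial weight of each offset is constant across the volume and is
// precomputed once; the intensity weight exp(-dI^2/(2 sigma_i^2)) is
// evaluated per voxel pair and never truncated.
//
// If `mask` is non-null, output values are computed only where mask != 0
// (other voxels are passed through unchanged). Because each output voxel
// depends only on *input* values, a masked evaluation is exact at the
// masked voxels; the grid-search objective uses this to avoid filtering
// voxels whose value it never reads.
// [[Rcpp::export]]
NumericVector bf_filter_cpp(const NumericVector& vol,
                            const IntegerVector& dims,
                            const NumericVector& spacing,
                            double sigma_xy, double sigma_z, double sigma_i,
                            const IntegerVector& radii,
                            Nullable<LogicalVector> mask = R_NilValue) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int rx = radii[0], ry = radii[1], rz = radii[2];
  const double inv2sxy = 1.0 / (2.0 * sigma_xy * sigma_xy);
  const double inv2sz  = 1.0 / (2.0 * sigma_z * sigma_z);
  const double inv2si  = 1.0 / (2.0 * sigma_i * sigma_i);
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];

  const int noff = (2 * rx + 1) * (2 * ry + 1) * (2 * rz + 1);
  std::vector<double> sw(noff);
  std::vector<int> odx(noff), ody(noff), odz(noff);
  int k = 0;
  for (int dz = -rz; dz <= rz; ++dz)
    for (int dy = -ry; dy <= ry; ++dy)
      for (int dx = -rx; dx <= rx; ++dx, ++k) {
        const double qx = dx * sx, qy = dy * sy, qz = dz * sz;
        sw[k] = std::exp(-(qx * qx + qy * qy) * inv2sxy - qz * qz * inv2sz);
        odx[k] = dx; ody[k] = dy; odz[k] = dz;
      }

  NumericVector out(clone(vol));
  const double* v = vol.begin();
  double* o = out.begin();
  const int* msk = nullptr;
  LogicalVector m_;
  if (mask.isNotNull()) { m_ = mask.get(); msk = m_.begin(); }

  const R_xlen_t sxstride = 1, systride = nx, szstride = (R_xlen_t)nx * ny;
  for (int iz = 0; iz < nz; ++iz) {
    for (int iy = 0; iy < ny; ++iy) {
      for (int ix = 0; ix < nx; ++ix) {
        const R_xlen_t idx = ix * sxstride + iy * systride + iz * szstride;
        if (msk && !msk[idx]) continue;
        const double im = v[idx];
        double num = 0.0, den = 0.0;
        for (int j = 0; j < noff; ++j) {
          const int jx = ix + odx[j];
          if (jx < 0 || jx >= nx) continue;
          const int jy = iy + ody[j];
          if (jy < 0 || jy >= ny) continue;
          const int jz = iz + odz[j];
          if (jz < 0 || jz >= nz) continue;
          const double in = v[jx + jy * systride + jz * szstride];
          const double di = in - im;
          const double w = sw[j] * std::exp(-di * di * inv2si);
          num += w * in;
          den += w;
        }
        o[idx] = num / den;
      }
    }
  }
  return out;
}
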