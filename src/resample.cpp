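#include <Rcpp.h>
using namespace Rcpp;

// Trilinear interpolation of `vol` (dims d[0..2]) at continuous 0-based voxel
// coordinates (x, y, z). Samples falling outside the grid return `fill`.
static inline double tri_sample(const double *vol, const int *d,
                                double x, double y, double z, double fill) {
  // tolerate round-off at the faces so a near-identity transform does not
  // drop edge voxels to the fill value
  const double eps = 1e-6;
  if (x < -eps || y < -eps || z < -eps ||
      x > d[0] - 1.0 + eps || y > d[1] - 1.0 + eps || z > d[2] - 1.0 + eps)
    return fill;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  // clamp so that x0+1 stays in range when x sits exactly on the top face
  if (x0 > d[0] - 2) x0 = d[0] - 2;
  if (y0 > d[1] - 2) y0 = d[1] - 2;
  if (z0 > d[2] - 2) z0 = d[2] - 2;
  if (x0 < 0) x0 = 0;
  if (y0 < 0) y0 = 0;
  if (z0 < 0) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const R_xlen_t sx = 1, sy = d[0], sz = (R_xlen_t)d[0] * d[1];
  const double *p = vol + x0 * sx + y0 * sy + z0 * sz;
  double c00 = p[0] * (1 - fx) + p[sx] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + sx] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + sx] * fx;
  double c11 = p[sy + sz] * (1 - fx) + p[sy + sz + sx] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Resample `moving` onto a target grid of dims `tdim` through the 4x4 affine
// `M` mapping target 0-based voxel indices to moving 0-based voxel indices.
// [[Rcpp::export]]
NumericVector c_affine_resample(NumericVector moving, IntegerVector mdim,
                                IntegerVector tdim, NumericMatrix M,
                                double fill) {
  int d[3] = {mdim[0], mdim[1], mdim[2]};
  int t0 = tdim[0], t1 = tdim[1], t2 = tdim[2];
  NumericVector out((R_xlen_t)t0 * t1 * t2);
  const double *mv = moving.begin();
  double m00 = M(0, 0), m01 = M(0, 1), m02 = M(0, 2), m03 = M(0, 3);
  double m10 = M(1, 0), m11 = M(1, 1), m12 = M(1, 2), m13 = M(1, 3);
  double m20 = M(2, 0), m21 = M(2, 1), m22 = M(2, 2), m23 = M(2, 3);
  R_xlen_t idx = 0;
  for (int k = 0; k < t2; ++k)
    for (int j = 0; j < t1; ++j) {
      double bx = m01 * j + m02 * k + m03;
      double by = m11 * j + m12 * k + m13;
      double bz = m21 * j + m22 * k + m23;
      for (int i = 0; i < t0; ++i, ++idx)
        out[idx] = tri_sample(mv, d, m00 * i + bx, m10 * i + by,
                              m20 * i + bz, fill);
    }
  out.attr("dim") = tdim;
  return out;
}

// Mean squared intensity difference between `fixed` and `moving` pulled back
// through `M` (fixed voxel -> moving voxel), over every `stride`-th voxel.
// [[Rcpp::export]]
double c_affine_mse(NumericVector fixed, IntegerVector fdim,
                    NumericVector moving, IntegerVector mdim,
                    NumericMatrix M, int stride, double fill) {
  int d[3] = {mdim[0], mdim[1], mdim[2]};
  int f0 = fdim[0], f1 = fdim[1], f2 = fdim[2];
  const double *fx = fixed.begin(), *mv = moving.begin();
  double m00 = M(0, 0), m01 = M(0, 1), m02 = M(0, 2), m03 = M(0, 3);
  double m10 = M(1, 0), m11 = M(1, 1), m12 = M(1, 2), m13 = M(1, 3);
  double m20 = M(2, 0), m21 = M(2, 1), m22 = M(2, 2), m23 = M(2, 3);
  double acc = 0.0;
  R_xlen_t n = 0;
  for (int k = 0; k < f2; k += stride)
    for (int j = 0; j < f1; j += stride) {
      double bx = m01 * j + m02 * k + m03;
      double by = m11 * j + m12 * k + m13;
      double bz = m21 * j + m22 * k + m23;
      R_xlen_t row = (R_xlen_t)j * f0 + (R_xlen_t)k * f0 * f1;
      for (int i = 0; i < f0; i += stride) {
        double s = tri_sample(mv, d, m00 * i + bx, m10 * i + by,
                              m20 * i + bz, fill);
        double diff = fx[row + i] - s;
        acc += diff * diff;
        ++n;
      }
    }
  return n > 0 ? acc / (double)n : R_PosInf;
}
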