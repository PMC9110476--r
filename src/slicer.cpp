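#include <Rcpp.h>
using namespace Rcpp;

// Plane-to-volume sampling shared by extract_slice and overlap_fraction.
// Conventions (must stay in lock-step with the R documentation and the R
// test oracle): 0-based voxel index k on an axis sits at physical
// (k + 0.5) * spacing - extent/2 mm; a point is inside the volume iff
// |p| <= extent/2 on every axis; interpolation coordinates are clamped to
// the voxel-centre range [0, n-1] so boundary points reuse edge voxels.

static inline double trilinear(const double* g, const int* d,
                               double ux, double uy, double uz) {
  int x0 = (int)std::floor(ux), y0 = (int)std::floor(uy), z0 = (int)std::floor(uz);
  if (x0 > d[0] - 2) x0 = d[0] - 2;
  if (y0 > d[1] - 2) y0 = d[1] - 2;
  if (z0 > d[2] - 2) z0 = d[2] - 2;
  if (x0 < 0) x0 = 0;
  if (y0 < 0) y0 = 0;
  if (z0 < 0) z0 = 0;
  double fx = ux - x0, fy = uy - y0, fz = uz - z0;
  const R_xlen_t nx = d[0], nxy = (R_xlen_t)d[0] * d[1];
  const double* p000 = g + x0 + nx * y0 + nxy * z0;
  double c000 = p000[0],       c100 = p000[1];
  double c010 = p000[nx],      c110 = p000[nx + 1];
  double c001 = p000[nxy],     c101 = p000[nxy + 1];
  double c011 = p000[nxy + nx], c111 = p000[nxy + nx + 1];
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
List slice_sample_cpp(NumericVector grid, NumericVector spacing,
                      NumericMatrix R, NumericVector t_mm,
                      double fov, int res) {
  IntegerVector dimv = grid.attr("dim");
  int d[3] = {dimv[0], dimv[1], dimv[2]};
  double ext2[3], sp[3];
  for (int k = 0; k < 3; ++k) {
    sp[k] = spacing[k];
    ext2[k] = d[k] * sp[k] / 2.0;
  }
  const double pix = fov / res;
  NumericMatrix out(res, res);
  const double* g = grid.begin();
  long inside_count = 0;
  for (int j = 0; j < res; ++j) {
    double x = (j + 0.5 - res / 2.0) * pix;
    for (int i = 0; i < res; ++i) {
      double y = (i + 0.5 - res / 2.0) * pix;
      double p0 = R(0, 0) * x + R(0, 1) * y + t_mm[0];
      double p1 = R(1, 0) * x + R(1, 1) * y + t_mm[1];
      double p2 = R(2, 0) * x + R(2, 1) * y + t_mm[2];
      bool inside = std::abs(p0) <= ext2[0] && std::abs(p1) <= ext2[1] &&
                    std::abs(p2) <= ext2[2];
      if (!inside) {
        out(i, j) = 0.0;
        continue;
      }
      ++inside_count;
      double ux = p0 / sp[0] + d[0] / 2.0 - 0.5;
      double uy = p1 / sp[1] + d[1] / 2.0 - 0.5;
      double uz = p2 / sp[2] + d[2] / 2.0 - 0.5;
      out(i, j) = trilinear(g, d, ux, uy, uz);
    }
  }
  return List::create(_["pixels"] = out,
                      _["overlap"] = (double)inside_count / ((double)res * res));
}

// [[Rcpp::export]]
double overlap_fraction_cpp(IntegerVector dimv, NumericVector spacing,
                            NumericMatrix R, NumericVector t_mm,
                            double fov, int res) {
  double ext2[3];
  for (int k = 0; k < 3; ++k) ext2[k] = dimv[k] * spacing[k] / 2.0;
  const double pix = fov / res;
  long inside_count = 0;
  for (int j = 0; j < res; ++j) {
    double x = (j + 0.5 - res / 2.0) * pix;
    for (int i = 0; i < res; ++i) {
      double y = (i + 0.5 - res / 2.0) * pix;
      double p0 = R(0, 0) * x + R(0, 1) * y + t_mm[0];
      double p1 = R(1, 0) * x + R(1, 1) * y + t_mm[1];
      double p2 = R(2, 0) * x + R(2, 1) * y + t_mm[2];
      if (std::abs(p0) <= ext2[0] && std::abs(p1) <= ext2[1] &&
          std::abs(p2) <= ext2[2])
        ++inside_count;
    }
  }
  return (double)inside_count / ((double)res * res);
}
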