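#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parallel-beam shadow projection of a volume rotated about the vertical
// (y) axis by angle_rad, integrating along z. vol is an R array [nx,ny,nz];
// returns an ny x nx image (rows = y = rotation axis). Bilinear in-plane
// interpolation; samples outside the grid contribute zero. The caller
// multiplies by the voxel size to turn the sum into a line integral.
// [[Rcpp::export]]
NumericMatrix cpp_project(NumericVector vol, int nx, int ny, int nz,
                          double angle_rad) {
  NumericMatrix out(ny, nx);
  const double cx = 0.5 * (nx - 1), cz = 0.5 * (nz - 1);
  const double c = std::cos(angle_rad), s = std::sin(angle_rad);
  const int nxy = nx * ny;
  const double *v = vol.begin();
  for (int ix = 0; ix < nx; ++ix) {
    const double dx = ix - cx;
    for (int iz = 0; iz < nz; ++iz) {
      const double dz = iz - cz;
      const double xs = cx + c * dx + s * dz;
      const double zs = cz - s * dx + c * dz;
      if (xs < 0 || xs > nx - 1 || zs < 0 || zs > nz - 1) continue;
      int x0 = (int)std::floor(xs); if (x0 == nx - 1) x0--;
      int z0 = (int)std::floor(zs); if (z0 == nz - 1) z0--;
      const double fx = xs - x0, fz = zs - z0;
      const double w00 = (1 - fx) * (1 - fz), w10 = fx * (1 - fz),
                   w01 = (1 - fx) * fz,       w11 = fx * fz;
      const int b00 = x0 + z0 * nxy, b10 = b00 + 1;
      const int b01 = b00 + nxy,     b11 = b01 + 1;
      double *o = &out(0, ix);
      for (int iy = 0; iy < ny; ++iy) {
        const int off = iy * nx;
        o[iy] += w00 * v[b00 + off] + w10 * v[b10 + off] +
                 w01 * v[b01 + off] + w11 * v[b11 + off];
      }
    }
  }
  return out;
}

// Unfiltered backprojection accumulator for one sinogram row. sino is
// n_angles x n_det (already ramp-filtered); angles in radians. Returns an
// n_det x n_det slice over (x, z). Detector coordinate convention:
// t = (x - c0) cos(theta) - (z - c0) sin(theta) + c0 + center_offset,
// matching cpp_project's rotation sense. Linear interpolation along the
// detector; rays falling off the detector contribute zero. Scaling by the
// angular step is applied by the caller.
// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix sino, NumericVector angles_rad,
                              double center_offset) {
  const int na = sino.nrow(), nd = sino.ncol();
  NumericMatrix out(nd, nd);
  const double c0 = 0.5 * (nd - 1);
  for (int a = 0; a < na; ++a) {
    const double c = std::cos(angles_rad[a]), s = std::sin(angles_rad[a]);
    for (int iz = 0; iz < nd; ++iz) {
      const double dz = iz - c0;
      for (int ix = 0; ix < nd; ++ix) {
        const double t = c0 + center_offset + (ix - c0) * c - dz * s;
        if (t < 0 || t > nd - 1) continue;
        int t0 = (int)std::floor(t); if (t0 == nd - 1) t0--;
        const double ft = t - t0;
        out(ix, iz) += (1 - ft) * sino(a, t0) + ft * sino(a, t0 + 1);
      }
    }
  }
  return out;
}

// Sub-pixel bilinear translation of an image (rows y, cols x) by
// (dx, dy) pixels; out-of-frame samples are zero.
// [[Rcpp::export]]
NumericMatrix cpp_translate(NumericMatrix img, double dx, double dy) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const double xs = j - dx;
    if (xs < 0 || xs > nc - 1) continue;
    int x0 = (int)std::floor(xs); if (x0 == nc - 1) x0--;
    const double fx = xs - x0;
    for (int i = 0; i < nr; ++i) {
      const double ys = i - dy;
      if (ys < 0 || ys > nr - 1) continue;
      int y0 = (int)std::floor(ys); if (y0 == nr - 1) y0--;
      const double fy = ys - y0;
      out(i, j) = (1 - fx) * ((1 - fy) * img(y0, x0) + fy * img(y0 + 1, x0)) +
                  fx * ((1 - fy) * img(y0, x0 + 1) + fy * img(y0 + 1, x0 + 1));
    }
  }
  return out;
}
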