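#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parallel-beam rotate-and-sum projector and linear-interpolation
// backprojector.  The rotation axis is the third array dimension (z);
// detector axis s lies along omega = (cos a, sin a) in the xy plane and
// the ray runs along omega_perp.  Coordinates are voxel units about the
// grid centre; callers scale by the voxel size.

static inline double sample2d(const double* img, int nx, int ny,
                              double x, double y) {
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  double fx = x - x0, fy = y - y0, v = 0.0;
  if (x0 >= 0 && x0 < nx) {
    if (y0 >= 0 && y0 < ny)       v += (1 - fx) * (1 - fy) * img[x0 + nx * y0];
    if (y0 + 1 >= 0 && y0 + 1 < ny) v += (1 - fx) * fy * img[x0 + nx * (y0 + 1)];
  }
  if (x0 + 1 >= 0 && x0 + 1 < nx) {
    if (y0 >= 0 && y0 < ny)       v += fx * (1 - fy) * img[x0 + 1 + nx * y0];
    if (y0 + 1 >= 0 && y0 + 1 < ny) v += fx * fy * img[x0 + 1 + nx * (y0 + 1)];
  }
  return v;
}

// vol: nx*ny*nz array; angles in radians.  Returns ndet(=nx) x nz x nang
// line integrals in units of (voxel value) * (voxel edge); multiply by the
// physical voxel size outside.
// [[Rcpp::export]]
NumericVector cpp_project(NumericVector vol, IntegerVector dims,
                          NumericVector angles, double tstep) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nang = angles.size(), ndet = nx;
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double cdet = (ndet - 1) / 2.0;
  const double tmax = 0.5 * std::sqrt((double)nx * nx + (double)ny * ny);
  const int nt = (int)std::ceil(2.0 * tmax / tstep) + 1;
  NumericVector out(ndet * nz * nang);
  const double* v = vol.begin();
  double* o = out.begin();
  for (int a = 0; a < nang; ++a) {
    const double ca = std::cos(angles[a]), sa = std::sin(angles[a]);
    for (int z = 0; z < nz; ++z) {
      const double* img = v + (size_t)nx * ny * z;
      double* row = o + (size_t)ndet * (z + (size_t)nz * a);
      for (int i = 0; i < ndet; ++i) {
        const double s = i - cdet;
        double acc = 0.0;
        for (int it = 0; it < nt; ++it) {
          const double t = -tmax + it * tstep;
          const double x = cx + s * ca - t * sa;
          const double y = cy + s * sa + t * ca;
          acc += sample2d(img, nx, ny, x, y);
        }
        row[i] = acc * tstep;
      }
    }
  }
  return out;
}

// sino: ndet x nz x nang filtered sinogram; returns nx x ny x nz volume.
// Caller multiplies by pi / nang.
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector sino, IntegerVector dims,
                              NumericVector angles, int nx, int ny) {
  const int ndet = dims[0], nz = dims[1], nang = dims[2];
  if (angles.size() != nang) stop("angle count mismatch");
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double cdet = (ndet - 1) / 2.0;
  NumericVector out((size_t)nx * ny * nz);
  const double* p = sino.begin();
  double* o = out.begin();
  std::vector<double> svals((size_t)nx * ny);
  for (int a = 0; a < nang; ++a) {
    const double ca = std::cos(angles[a]), sa = std::sin(angles[a]);
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x)
        svals[x + (size_t)nx * y] = (x - cx) * ca + (y - cy) * sa + cdet;
    for (int z = 0; z < nz; ++z) {
      const double* row = p + (size_t)ndet * (z + (size_t)nz * a);
      double* slab = o + (size_t)nx * ny * z;
      for (size_t j = 0; j < (size_t)nx * ny; ++j) {
        const double s = svals[j];
        const int s0 = (int)std::floor(s);
        const double fs = s - s0;
        double val = 0.0;
        if (s0 >= 0 && s0 < ndet) val += (1 - fs) * row[s0];
        if (s0 + 1 >= 0 && s0 + 1 < ndet) val += fs * row[s0 + 1];
        slab[j] += val;
      }
    }
  }
  return out;
}
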