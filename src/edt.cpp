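// Anisotropy-aware Euclidean distance transform.
// Felzenszwalb & Huttenlocher (2012) separable lower-envelope algorithm,
// generalized to per-axis sampling steps so distances come out in physical
// units (nm) on the 8 x 8 x 50 nm grids typical of serial block-face SEM.
//
// Array convention used throughout the package: R arrays indexed [z, y, x]
// with z fastest (dim = c(nz, ny, nx)); spacing = c(hz, hy, hx) in nm.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double DT_INF = 1e30;

// 1D squared-distance transform with sample step h (envelope in index units,
// parabola weight h^2 so the result is in squared physical units).
static void dt1d(const double* f, double* d, int n, double h2,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s = 0.0;
    while (true) {
      int p = v[k];
      s = ((f[q] + h2 * (double)q * q) - (f[p] + h2 * (double)p * p)) /
          (2.0 * h2 * (double)(q - p));
      if (k > 0 && s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = h2 * dq * dq + f[v[k]];
  }
}

// Distance (nm) from every TRUE voxel to the nearest FALSE voxel *center*.
// FALSE voxels get 0. If no FALSE voxel exists, distances are DT_INF-scale.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? DT_INF : 0.0;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  double hz2 = spacing[0] * spacing[0];
  double hy2 = spacing[1] * spacing[1];
  double hx2 = spacing[2] * spacing[2];

  // pass 1: along z (stride 1)
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      dt1d(&g[base], &d[0], nz, hz2, v, z);
      for (int q = 0; q < nz; ++q) g[base + q] = d[q];
    }
  }
  // pass 2: along y (stride nz)
  for (int x = 0; x < nx; ++x) {
    for (int zz = 0; zz < nz; ++zz) {
      R_xlen_t base = zz + (R_xlen_t)nz * ny * x;
      for (int q = 0; q < ny; ++q) f[q] = g[base + (R_xlen_t)nz * q];
      dt1d(&f[0], &d[0], ny, hy2, v, z);
      for (int q = 0; q < ny; ++q) g[base + (R_xlen_t)nz * q] = d[q];
    }
  }
  // pass 3: along x (stride nz*ny)
  R_xlen_t sx = (R_xlen_t)nz * ny;
  for (int y = 0; y < ny; ++y) {
    for (int zz = 0; zz < nz; ++zz) {
      R_xlen_t base = zz + (R_xlen_t)nz * y;
      for (int q = 0; q < nx; ++q) f[q] = g[base + sx * q];
      dt1d(&f[0], &d[0], nx, hx2, v, z);
      for (int q = 0; q < nx; ++q) g[base + sx * q] = d[q];
    }
  }

  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  out.attr("dim") = dim;
  return out;
}
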