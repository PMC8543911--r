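#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double DINF = std::numeric_limits<double>::infinity();

// 1D lower-envelope squared distance transform (Felzenszwalb-Huttenlocher),
// in units of the grid step; propagates the argmin so a feature (nearest-site)
// transform falls out of the same pass.
static void dt1d(std::vector<double>& f, std::vector<int>& feat, int n,
                 std::vector<double>& d, std::vector<int>& df,
                 std::vector<int>& v, std::vector<double>& z) {
  int q0 = 0;
  while (q0 < n && f[q0] == DINF) ++q0;
  if (q0 == n) {
    for (int q = 0; q < n; ++q) { d[q] = DINF; df[q] = 0; }
    return;
  }
  int k = 0;
  v[0] = q0; z[0] = -DINF; z[1] = DINF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == DINF) continue;
    double s = 0.0;
    while (true) {
      int p = v[k];
      s = ((f[q] + (double)q * q) - (f[p] + (double)p * p)) / (2.0 * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = DINF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = (double)(q - p) * (q - p) + f[p];
    df[q] = feat[p];
  }
}

// Euclidean distance transform to the nearest site voxel, anisotropic spacing.
// Returns squared distance in mm^2 and the 1-based linear index of the nearest
// site (0 where no site exists).
// [[Rcpp::export(name = ".edt_cpp")]]
List edt_cpp(LogicalVector sites, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  std::vector<double> D(nvox);
  std::vector<int> F(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) {
    D[i] = sites[i] ? 0.0 : DINF;
    F[i] = sites[i] ? (int)(i + 1) : 0;
  }
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dcol(nmax), z(nmax + 1);
  std::vector<int> ft(nmax), dfcol(nmax), v(nmax);

  // pass along x
  {
    const double w2 = spacing[0] * spacing[0];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = 0; i < nx; ++i) { f[i] = D[base + i] / w2; ft[i] = F[base + i]; }
        dt1d(f, ft, nx, dcol, dfcol, v, z);
        for (int i = 0; i < nx; ++i) {
          D[base + i] = (dcol[i] == DINF) ? DINF : dcol[i] * w2;
          F[base + i] = dfcol[i];
        }
      }
  }
  // pass along y
  {
    const double w2 = spacing[1] * spacing[1];
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t base = i + (R_xlen_t)nx * ny * k;
        for (int j = 0; j < ny; ++j) { f[j] = D[base + (R_xlen_t)nx * j] / w2; ft[j] = F[base + (R_xlen_t)nx * j]; }
        dt1d(f, ft, ny, dcol, dfcol, v, z);
        for (int j = 0; j < ny; ++j) {
          D[base + (R_xlen_t)nx * j] = (dcol[j] == DINF) ? DINF : dcol[j] * w2;
          F[base + (R_xlen_t)nx * j] = dfcol[j];
        }
      }
  }
  // pass along z
  {
    const double w2 = spacing[2] * spacing[2];
    const R_xlen_t stride = (R_xlen_t)nx * ny;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t base = i + (R_xlen_t)nx * j;
        for (int k = 0; k < nz; ++k) { f[k] = D[base + stride * k] / w2; ft[k] = F[base + stride * k]; }
        dt1d(f, ft, nz, dcol, dfcol, v, z);
        for (int k = 0; k < nz; ++k) {
          D[base + stride * k] = (dcol[k] == DINF) ? DINF : dcol[k] * w2;
          F[base + stride * k] = dfcol[k];
        }
      }
  }
  NumericVector dist2(nvox);
  IntegerVector feat(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) { dist2[i] = D[i]; feat[i] = F[i]; }
  return List::create(_["dist2"] = dist2, _["feature"] = feat);
}
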