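#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable Gaussian smoothing, sigma per axis in voxel units, reflective borders.
// [[Rcpp::export(name = ".gauss3_cpp")]]
NumericVector gauss3_cpp(NumericVector vol, IntegerVector dim, NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(vol.begin(), vol.end()), b(nvox);
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const int n[3] = {nx, ny, nz};
  const R_xlen_t str[3] = {sx, sy, sz};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * r + 1);
    double tot = 0;
    for (int t = -r; t <= r; ++t) { ker[t + r] = std::exp(-0.5 * t * t / (s * s)); tot += ker[t + r]; }
    for (double& kv : ker) kv /= tot;
    const int na = n[ax];
    const R_xlen_t sa = str[ax];
    // iterate over all lines along ax
    int o1 = (ax == 0) ? 1 : 0;
    int o2 = (ax == 2) ? 1 : 2;
    const int n1 = n[o1], n2 = n[o2];
    const R_xlen_t s1 = str[o1], s2 = str[o2];
    for (int j2 = 0; j2 < n2; ++j2)
      for (int j1 = 0; j1 < n1; ++j1) {
        R_xlen_t base = s1 * j1 + s2 * j2;
        for (int i = 0; i < na; ++i) {
          double acc = 0;
          for (int t = -r; t <= r; ++t) acc += ker[t + r] * a[base + sa * reflect(i + t, na)];
          b[base + sa * i] = acc;
        }
      }
    std::swap(a, b);
  }
  NumericVector out(nvox);
  std::copy(a.begin(), a.end(), out.begin());
  return out;
}

static inline double tri_sample(const double* v, int nx, int ny, int nz,
                                double x, double y, double z,
                                bool clampEdge, double outside) {
  if (!clampEdge) {
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
      return outside;
  }
  if (x < 0) x = 0; if (y < 0) y = 0; if (z < 0) z = 0;
  if (x > nx - 1) x = nx - 1; if (y > ny - 1) y = ny - 1; if (z > nz - 1) z = nz - 1;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 > nx - 2) i0 = nx - 2; if (j0 > ny - 2) j0 = ny - 2; if (k0 > nz - 2) k0 = nz - 2;
  if (i0 < 0) i0 = 0; if (j0 < 0) j0 = 0; if (k0 < 0) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  const double* p = v + i0 + sy * j0 + sz * k0;
  double c00 = p[0] * (1 - fx) + p[1] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + 1] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + 1] * fx;
  double c11 = p[sy + sz] * (1 - fx) + p[sy + sz + 1] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Sample a volume at arbitrary continuous voxel coordinates (0-based).
// [[Rcpp::export(name = ".sample_tri_cpp")]]
NumericVector sample_tri_cpp(NumericVector vol, IntegerVector dim, NumericMatrix pts,
                             bool clamp_edge, double outside) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if (nx < 2 || ny < 2 || nz < 2) stop("volume too small for interpolation");
  R_xlen_t np = pts.nrow();
  NumericVector out(np);
  const double* v = REAL(vol);
  for (R_xlen_t p = 0; p < np; ++p)
    out[p] = tri_sample(v, nx, ny, nz, pts(p, 0), pts(p, 1), pts(p, 2), clamp_edge, outside);
  return out;
}

// out(x) = vol(x + u(x)); displacement in voxel units; outside -> `outside` value.
// [[Rcpp::export(name = ".warp_cpp")]]
NumericVector warp_cpp(NumericVector vol, IntegerVector dim,
                       NumericVector ux, NumericVector uy, NumericVector uz,
                       bool clamp_edge, double outside) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(nvox);
  const double* v = REAL(vol);
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx)
        out[idx] = tri_sample(v, nx, ny, nz,
                              i + ux[idx], j + uy[idx], k + uz[idx], clamp_edge, outside);
  return out;
}

// c = a o b on the shared grid: c(x) = b(x) + a(x + b(x)). Voxel units.
// [[Rcpp::export(name = ".compose_disp_cpp")]]
List compose_disp_cpp(List a, List b, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector ax = a[0], ay = a[1], az = a[2];
  NumericVector bx = b[0], by = b[1], bz = b[2];
  NumericVector cx(nvox), cy(nvox), cz(nvox);
  const double* pax = REAL(ax); const double* pay = REAL(ay); const double* paz = REAL(az);
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double x = i + bx[idx], y = j + by[idx], z = k + bz[idx];
        cx[idx] = bx[idx] + tri_sample(pax, nx, ny, nz, x, y, z, true, 0.0);
        cy[idx] = by[idx] + tri_sample(pay, nx, ny, nz, x, y, z, true, 0.0);
        cz[idx] = bz[idx] + tri_sample(paz, nx, ny, nz, x, y, z, true, 0.0);
      }
  return List::create(cx, cy, cz);
}

// Jacobian determinant of x + u(x), central differences (one-sided at borders).
// [[Rcpp::export(name = ".jacdet_cpp")]]
NumericVector jacdet_cpp(NumericVector ux, NumericVector uy, NumericVector uz,
                         IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  NumericVector out(nvox);
  const double* u[3] = {REAL(ux), REAL(uy), REAL(uz)};
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double J[3][3];
        const int pos[3] = {i, j, k};
        const int n[3] = {nx, ny, nz};
        const R_xlen_t str[3] = {1, sy, sz};
        for (int c = 0; c < 3; ++c) {       // component
          for (int d = 0; d < 3; ++d) {     // derivative axis
            int lo = pos[d] > 0 ? 1 : 0;
            int hi = pos[d] < n[d] - 1 ? 1 : 0;
            double num = u[c][idx + hi * str[d]] - u[c][idx - lo * str[d]];
            double den = (double)(hi + lo);
            J[c][d] = (den > 0 ? num / den : 0.0) + (c == d ? 1.0 : 0.0);
          }
        }
        out[idx] = J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1])
                 - J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0])
                 + J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
      }
  return out;
}

// Central-difference gradient, voxel units.
// [[Rcpp::export(name = ".gradient3_cpp")]]
List gradient3_cpp(NumericVector vol, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const R_xlen_t str[3] = {1, nx, (R_xlen_t)nx * ny};
  NumericVector gx(nvox), gy(nvox), gz(nvox);
  NumericVector* g[3] = {&gx, &gy, &gz};
  const double* v = REAL(vol);
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        const int pos[3] = {i, j, k};
        const int n[3] = {nx, ny, nz};
        for (int d = 0; d < 3; ++d) {
          int lo = pos[d] > 0 ? 1 : 0;
          int hi = pos[d] < n[d] - 1 ? 1 : 0;
          double den = (double)(hi + lo);
          (*g[d])[idx] = den > 0 ? (v[idx + hi * str[d]] - v[idx - lo * str[d]]) / den : 0.0;
        }
      }
  return List::create(gx, gy, gz);
}

// Trilinear resampling of a whole volume onto a new grid covering the same
// physical extent (used by the multiresolution pyramid).
// [[Rcpp::export(name = ".resize_cpp")]]
NumericVector resize_cpp(NumericVector vol, IntegerVector dim, IntegerVector newdim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int mx = newdim[0], my = newdim[1], mz = newdim[2];
  const R_xlen_t nvox = (R_xlen_t)mx * my * mz;
  NumericVector out(nvox);
  const double* v = REAL(vol);
  double fx = (double)(nx - 1) / std::max(1, mx - 1);
  double fy = (double)(ny - 1) / std::max(1, my - 1);
  double fz = (double)(nz - 1) / std::max(1, mz - 1);
  R_xlen_t idx = 0;
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i, ++idx)
        out[idx] = tri_sample(v, nx, ny, nz, i * fx, j * fy, k * fz, true, 0.0);
  return out;
}
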