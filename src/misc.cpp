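#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Rasterize a sampled center surface into a voxel grid: for every voxel within
// `halfw[p] + margin` (voxel units) of some sample point, record the distance to
// and index of the nearest sample. Used by the ribbon phantom generator; voxels
// left at +Inf belong to the background.
// [[Rcpp::export(name = ".splat_cpp")]]
List splat_cpp(NumericMatrix pts, NumericVector halfw, double margin, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector dist(nvox, R_PosInf);
  IntegerVector idx(nvox, 0);
  const R_xlen_t np = pts.nrow();
  for (R_xlen_t p = 0; p < np; ++p) {
    double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    double r = halfw[p] + margin;
    int i0 = std::max(0, (int)std::ceil(px - r)), i1 = std::min(nx - 1, (int)std::floor(px + r));
    int j0 = std::max(0, (int)std::ceil(py - r)), j1 = std::min(ny - 1, (int)std::floor(py + r));
    int k0 = std::max(0, (int)std::ceil(pz - r)), k1 = std::min(nz - 1, (int)std::floor(pz + r));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j) {
        R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = i0; i <= i1; ++i) {
          double d = std::sqrt((i - px) * (i - px) + (j - py) * (j - py) + (k - pz) * (k - pz));
          if (d < dist[base + i]) { dist[base + i] = d; idx[base + i] = (int)(p + 1); }
        }
      }
  }
  return List::create(_["dist"] = dist, _["index"] = idx);
}

// Randomized region growing inside a mask (6-connectivity): grow a connected
// blob of n_target voxels from start (1-based linear index), picking the next
// frontier voxel with R's RNG so blobs are seeded-deterministic.
// [[Rcpp::export(name = ".region_grow_cpp")]]
IntegerVector region_grow_cpp(LogicalVector mask, IntegerVector dim, int start, int n_target) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t str[3] = {1, nx, (R_xlen_t)nx * ny};
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  std::vector<char> in(nvox, 0), infront(nvox, 0);
  std::vector<R_xlen_t> blob, frontier;
  R_xlen_t s = start - 1;
  if (s < 0 || s >= nvox || !mask[s]) stop("start voxel not inside mask");
  RNGScope scope;
  in[s] = 1; blob.push_back(s);
  auto push_nb = [&](R_xlen_t v) {
    int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((R_xlen_t)nx * ny));
    const int pos[3] = {i, j, k}, n[3] = {nx, ny, nz};
    for (int d = 0; d < 3; ++d)
      for (int sgn = -1; sgn <= 1; sgn += 2) {
        int q = pos[d] + sgn;
        if (q < 0 || q >= n[d]) continue;
        R_xlen_t w = v + sgn * str[d];
        if (mask[w] && !in[w] && !infront[w]) { infront[w] = 1; frontier.push_back(w); }
      }
  };
  push_nb(s);
  while ((int)blob.size() < n_target && !frontier.empty()) {
    R_xlen_t pick = (R_xlen_t)std::floor(unif_rand() * frontier.size());
    if (pick >= (R_xlen_t)frontier.size()) pick = frontier.size() - 1;
    R_xlen_t v = frontier[pick];
    frontier[pick] = frontier.back(); frontier.pop_back();
    infront[v] = 0;
    if (in[v]) continue;
    in[v] = 1; blob.push_back(v);
    push_nb(v);
  }
  IntegerVector out(blob.size());
  for (size_t t = 0; t < blob.size(); ++t) out[t] = (int)(blob[t] + 1);
  return out;
}

// Max-ball coverage: for every voxel within radius[p] + tol of skeleton
// element p, record the largest such radius. Used to assign boundary-point
// thickness as twice the largest inscribed ball reaching the point.
// [[Rcpp::export(name = ".ball_max_cpp")]]
NumericVector ball_max_cpp(NumericMatrix pts, NumericVector radius_vox,
                           double tol_vox, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(nvox, 0.0);
  const R_xlen_t np = pts.nrow();
  for (R_xlen_t p = 0; p < np; ++p) {
    double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    double r = radius_vox[p] + tol_vox;
    double r2 = r * r;
    int i0 = std::max(0, (int)std::ceil(px - r)), i1 = std::min(nx - 1, (int)std::floor(px + r));
    int j0 = std::max(0, (int)std::ceil(py - r)), j1 = std::min(ny - 1, (int)std::floor(py + r));
    int k0 = std::max(0, (int)std::ceil(pz - r)), k1 = std::min(nz - 1, (int)std::floor(pz + r));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j) {
        R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = i0; i <= i1; ++i) {
          double d2 = (i - px) * (i - px) + (j - py) * (j - py) + (k - pz) * (k - pz);
          if (d2 <= r2 && radius_vox[p] > out[base + i]) out[base + i] = radius_vox[p];
        }
      }
  }
  return out;
}

// Three-pass boundary-thickness assignment. Pass 0: per voxel, the largest
// covering-ball radius. Pass 1: among covering elements with radius at
// least `ratio` times that maximum, the distance of the nearest. Pass 2:
// the largest radius among qualifying elements within 0.75 voxels of that
// nearest distance. Localizes thickness at genuine steps while ignoring
// small spurious medial elements and sub-maximal near neighbors.
// [[Rcpp::export(name = ".ball_assign_cpp")]]
List ball_assign_cpp(NumericMatrix pts, NumericVector radius_vox,
                     double tol_vox, double ratio, IntegerVector dim,
                     double window_vox = 0.75) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector rmax(nvox, 0.0), bestd(nvox, R_PosInf);
  IntegerVector pick(nvox, 0);
  const R_xlen_t np = pts.nrow();
  for (int pass = 0; pass < 3; ++pass) {
    for (R_xlen_t p = 0; p < np; ++p) {
      double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
      double r = radius_vox[p] + tol_vox;
      double r2 = r * r;
      int i0 = std::max(0, (int)std::ceil(px - r)), i1 = std::min(nx - 1, (int)std::floor(px + r));
      int j0 = std::max(0, (int)std::ceil(py - r)), j1 = std::min(ny - 1, (int)std::floor(py + r));
      int k0 = std::max(0, (int)std::ceil(pz - r)), k1 = std::min(nz - 1, (int)std::floor(pz + r));
      for (int k = k0; k <= k1; ++k)
        for (int j = j0; j <= j1; ++j) {
          R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
          for (int i = i0; i <= i1; ++i) {
            double d2 = (i - px) * (i - px) + (j - py) * (j - py) + (k - pz) * (k - pz);
            if (d2 > r2) continue;
            if (pass == 0) {
              if (radius_vox[p] > rmax[base + i]) rmax[base + i] = radius_vox[p];
            } else if (pass == 1) {
              if (radius_vox[p] + 1e-12 >= ratio * rmax[base + i] && d2 < bestd[base + i])
                bestd[base + i] = d2;
            } else {
              if (radius_vox[p] + 1e-12 >= ratio * rmax[base + i] &&
                  std::sqrt(d2) <= std::sqrt(bestd[base + i]) + window_vox) {
                int cur = pick[base + i];
                if (cur == 0 || radius_vox[p] > radius_vox[cur - 1])
                  pick[base + i] = (int)(p + 1);
              }
            }
          }
        }
    }
  }
  return List::create(_["pick"] = pick, _["rmax"] = rmax);
}

// Ball-depth field: max over elements of (radius - distance to element
// center). A medial element whose own radius is clearly below this depth
// at its center is contained in a larger inscribed ball and is not
// maximal.
// [[Rcpp::export(name = ".ball_depth_cpp")]]
NumericVector ball_depth_cpp(NumericMatrix pts, NumericVector radius_vox,
                             IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(nvox, 0.0);
  const R_xlen_t np = pts.nrow();
  for (R_xlen_t p = 0; p < np; ++p) {
    double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    double r = radius_vox[p];
    int i0 = std::max(0, (int)std::ceil(px - r)), i1 = std::min(nx - 1, (int)std::floor(px + r));
    int j0 = std::max(0, (int)std::ceil(py - r)), j1 = std::min(ny - 1, (int)std::floor(py + r));
    int k0 = std::max(0, (int)std::ceil(pz - r)), k1 = std::min(nz - 1, (int)std::floor(pz + r));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j) {
        R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = i0; i <= i1; ++i) {
          double dd = r - std::sqrt((i - px) * (i - px) + (j - py) * (j - py) + (k - pz) * (k - pz));
          if (dd > out[base + i]) out[base + i] = dd;
        }
      }
  }
  return out;
}
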