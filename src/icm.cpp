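#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Iterated conditional modes for a Potts-regularized labeling.
// logf: nvox x L matrix of log vote fractions (already smoothed in R);
// init: 0-based label indices; upd: voxels free to change (others fixed);
// weight: Potts coupling per 6-neighbor face. Raster sweep order, flips only
// on strict improvement, ties broken toward the lowest label index.
// [[Rcpp::export(name = ".icm_cpp")]]
List icm_cpp(NumericMatrix logf, IntegerVector dim, IntegerVector init,
             LogicalVector upd, double weight, int max_sweeps) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const int L = logf.ncol();
  std::vector<int> lab(init.begin(), init.end());
  const R_xlen_t str[3] = {1, nx, (R_xlen_t)nx * ny};

  auto energy = [&]() {
    double e = 0;
    R_xlen_t idx = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++idx) {
          e += logf(idx, lab[idx]);
          if (i + 1 < nx && lab[idx] == lab[idx + str[0]]) e += weight;
          if (j + 1 < ny && lab[idx] == lab[idx + str[1]]) e += weight;
          if (k + 1 < nz && lab[idx] == lab[idx + str[2]]) e += weight;
        }
    return e;
  };

  std::vector<double> etrace;
  etrace.push_back(energy());
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    int nflip = 0;
    R_xlen_t idx = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++idx) {
          if (!upd[idx]) continue;
          int nb[6]; int nn = 0;
          if (i > 0) nb[nn++] = lab[idx - str[0]];
          if (i + 1 < nx) nb[nn++] = lab[idx + str[0]];
          if (j > 0) nb[nn++] = lab[idx - str[1]];
          if (j + 1 < ny) nb[nn++] = lab[idx + str[1]];
          if (k > 0) nb[nn++] = lab[idx - str[2]];
          if (k + 1 < nz) nb[nn++] = lab[idx + str[2]];
          int cur = lab[idx];
          int best = cur;
          double bestv = logf(idx, cur);
          for (int t = 0; t < nn; ++t) if (nb[t] == cur) bestv += weight;
          for (int l = 0; l < L; ++l) {
            if (l == cur) continue;
            double val = logf(idx, l);
            for (int t = 0; t < nn; ++t) if (nb[t] == l) val += weight;
            if (val > bestv + 1e-12 || (val > bestv - 1e-12 && l < best && val >= bestv)) {
              // strict improvement only; tie falls back to current assignment
              if (val > bestv + 1e-12) { bestv = val; best = l; }
            }
          }
          if (best != cur) { lab[idx] = best; ++nflip; }
        }
    etrace.push_back(energy());
    if (nflip == 0) break;
  }
  IntegerVector out(nvox);
  std::copy(lab.begin(), lab.end(), out.begin());
  return List::create(_["labels"] = out, _["energy"] = NumericVector(etrace.begin(), etrace.end()));
}
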