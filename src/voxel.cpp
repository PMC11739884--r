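#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a 3D logical mask.
// connectivity: 6 (face) or 26 (face+edge+corner). Returns integer array of
// component ids (0 = background), components numbered in scan order.
// [[Rcpp::export(name = ".cc_label_mask")]]
IntegerVector cc_label_mask(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dx, dy, dz});
      }

  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int comp = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++comp;
    lab[s] = comp;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int k = (int)(cur / ((R_xlen_t)nx * ny));
      int rem = (int)(cur % ((R_xlen_t)nx * ny));
      int j = rem / nx, i = rem % nx;
      for (size_t o = 0; o < offs.size(); ++o) {
        int ii = i + offs[o][0], jj = j + offs[o][1], kk = k + offs[o][2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        R_xlen_t q = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
        if (mask[q] && lab[q] == 0) {
          lab[q] = comp;
          stack.push_back(q);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  lab.attr("n_components") = comp;
  return lab;
}
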