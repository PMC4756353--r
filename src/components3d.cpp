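#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labelling on a logical mask stored column-major
// with dims (nz, ny, nx). Connectivity 6 (face) or 26 (face+edge+corner).
// Labels are assigned in raster-scan order starting at 1; background is 0.
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims,
                          int connectivity = 26) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");

  // neighbour offsets in (dz, dy, dx)
  std::vector<int> dzs, dys, dxs;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manh != 1) continue;
        dzs.push_back(dz); dys.push_back(dy); dxs.push_back(dx);
      }
  const int nn = (int)dzs.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> queue;
  queue.reserve(1024);
  int next_label = 0;

  for (R_xlen_t idx = 0; idx < n; ++idx) {
    if (!mask[idx] || labels[idx] != 0) continue;
    ++next_label;
    labels[idx] = next_label;
    queue.clear();
    queue.push_back(idx);
    while (!queue.empty()) {
      R_xlen_t cur = queue.back();
      queue.pop_back();
      int z = (int)(cur % nz);
      R_xlen_t rest = cur / nz;
      int y = (int)(rest % ny);
      int x = (int)(rest / ny);
      for (int k = 0; k < nn; ++k) {
        int zz = z + dzs[k], yy = y + dys[k], xx = x + dxs[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t nidx = (R_xlen_t)zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[nidx] && labels[nidx] == 0) {
          labels[nidx] = next_label;
          queue.push_back(nidx);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  labels.attr("n_components") = next_label;
  return labels;
}
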