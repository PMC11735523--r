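// 3-D connected-component labelling on binary volumes by breadth-first
// search.  Used both on voxel-space vessel masks (small-cluster pruning)
// and on the stride-spaced lattice of thresholded window probabilities.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = static_cast<R_xlen_t>(d1) * d2 * d3;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  std::vector<int> off1, off2, off3;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (man == 0) continue;
        if (connectivity == 6 && man > 1) continue;
        if (connectivity == 18 && man > 2) continue;
        off1.push_back(dx); off2.push_back(dy); off3.push_back(dz);
      }

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> queue;
  queue.reserve(1024);
  int cur = 0;
  const R_xlen_t plane = static_cast<R_xlen_t>(d1) * d2;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++cur;
    labels[s] = cur;
    queue.clear();
    queue.push_back(s);
    while (!queue.empty()) {
      const R_xlen_t v = queue.back();
      queue.pop_back();
      const int z = static_cast<int>(v / plane);
      const int rem = static_cast<int>(v % plane);
      const int y = rem / d1;
      const int x = rem % d1;
      for (size_t j = 0; j < off1.size(); ++j) {
        const int nx = x + off1[j], ny = y + off2[j], nz = z + off3[j];
        if (nx < 0 || nx >= d1 || ny < 0 || ny >= d2 || nz < 0 || nz >= d3)
          continue;
        const R_xlen_t w = nx + static_cast<R_xlen_t>(d1) * ny + plane * nz;
        if (mask[w] && labels[w] == 0) {
          labels[w] = cur;
          queue.push_back(w);
        }
      }
    }
  }
  labels.attr("n_components") = cur;
  return labels;
}
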