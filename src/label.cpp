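#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connected component labelling of a binary volume (iterative BFS).
// Labels are assigned in scan order starting at 1; background is 0.
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<size_t> queue;
  int next = 0;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    queue.clear();
    queue.push_back(s);
    size_t head = 0;
    while (head < queue.size()) {
      size_t c = queue[head++];
      int x = (int)(c % nx);
      int y = (int)((c / nx) % ny);
      int z = (int)(c / ((size_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int qx = x + dx, qy = y + dy, qz = z + dz;
            if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz) continue;
            size_t q = (size_t)qx + (size_t)nx * ((size_t)qy + (size_t)ny * qz);
            if (mask[q] && lab[q] == 0) { lab[q] = next; queue.push_back(q); }
          }
    }
  }
  return lab;
}
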