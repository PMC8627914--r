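#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstdint>
using namespace Rcpp;

// 3-D curve thinning by distance-ordered homotopic erosion: simple points
// are deleted in increasing order of their Euclidean distance to the
// background, with curve endpoints (voxels with a single foreground
// neighbour) preserved.  Medial-axis voxels carry the locally largest
// distance values, so they are deleted last and the skeleton follows the
// centerline of tubular structures all the way into branch tips.  A voxel
// is simple iff deleting it changes neither the number of 26-connected
// foreground components nor the number of 6-connected background
// components in its 3x3x3 neighbourhood (Bertrand & Malandain topological
// numbers: C* == 1 and Cbar == 1).

namespace {

struct Grid {
  const uint8_t* v;
  int nx, ny, nz;
  inline bool at(int x, int y, int z) const {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return false;
    return v[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z)] != 0;
  }
};

// Collect the 3x3x3 neighbourhood (center at (1,1,1)) into cube[27],
// index = dx+1 + 3*(dy+1) + 9*(dz+1).
inline void neighbourhood(const Grid& g, int x, int y, int z, bool cube[27]) {
  int n = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++n)
        cube[n] = g.at(x + dx, y + dy, z + dz);
}

inline int cidx(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

// Number of 26-connected components of foreground within N26 (center removed).
int c_star(const bool cube[27]) {
  bool fg[27];
  for (int i = 0; i < 27; ++i) fg[i] = cube[i];
  fg[13] = false;  // remove center
  int label[27];
  for (int i = 0; i < 27; ++i) label[i] = -1;
  int ncomp = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (!fg[s] || label[s] >= 0) continue;
    int top = 0;
    stack[top++] = s;
    label[s] = ncomp;
    while (top > 0) {
      int c = stack[--top];
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int qx = cx + dx, qy = cy + dy, qz = cz + dz;
            if (qx < 0 || qy < 0 || qz < 0 || qx > 2 || qy > 2 || qz > 2) continue;
            int q = qx + 3 * qy + 9 * qz;
            if (fg[q] && label[q] < 0) { label[q] = ncomp; stack[top++] = q; }
          }
    }
    ++ncomp;
  }
  return ncomp;
}

// Number of 6-connected components of background restricted to N18 that are
// 6-adjacent to the center.
int c_bar(const bool cube[27]) {
  // N18 membership: |dx|+|dy|+|dz| in {1,2} and not a corner (|dx|=|dy|=|dz|=1).
  bool in18[27];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        in18[cidx(dx, dy, dz)] = (m == 1 || m == 2) && !(std::abs(dx) == 1 && std::abs(dy) == 1 && std::abs(dz) == 1);
      }
  bool bg[27];
  for (int i = 0; i < 27; ++i) bg[i] = in18[i] && !cube[i];
  int label[27];
  for (int i = 0; i < 27; ++i) label[i] = -1;
  int ncomp_adj = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (!bg[s] || label[s] >= 0) continue;
    int comp = s + 1;  // any positive marker
    int top = 0;
    stack[top++] = s;
    label[s] = comp;
    bool touches_face = false;
    while (top > 0) {
      int c = stack[--top];
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      int m = std::abs(cx - 1) + std::abs(cy - 1) + std::abs(cz - 1);
      if (m == 1) touches_face = true;
      const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int qx = cx + off[k][0], qy = cy + off[k][1], qz = cz + off[k][2];
        if (qx < 0 || qy < 0 || qz < 0 || qx > 2 || qy > 2 || qz > 2) continue;
        int q = qx + 3 * qy + 9 * qz;
        if (bg[q] && label[q] < 0) { label[q] = comp; stack[top++] = q; }
      }
    }
    if (touches_face) ++ncomp_adj;
  }
  return ncomp_adj;
}

inline bool is_simple(const bool cube[27]) {
  return c_star(cube) == 1 && c_bar(cube) == 1;
}

inline int n_fg_neighbours(const bool cube[27]) {
  int n = 0;
  for (int i = 0; i < 27; ++i) if (i != 13 && cube[i]) ++n;
  return n;
}

}  // namespace

// [[Rcpp::export]]
LogicalVector cpp_thin(LogicalVector mask, IntegerVector dims, NumericVector dist,
                       double anchor_delta) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<uint8_t> img(n);
  for (size_t i = 0; i < n; ++i) img[i] = mask[i] ? 1 : 0;
  Grid g{img.data(), nx, ny, nz};

  // Distance-ridge anchors: a voxel at a local maximum (or plateau, within
  // anchor_delta) of the distance field lies on the medial axis and is
  // never deleted, so a tube's axial ridge -- and with it every short side
  // branch -- survives erosion.  The ridge declining into a rounded tip has
  // a strictly larger proximal neighbour and is not anchored, which keeps
  // tip spikes removable.  anchor_delta < 0 disables anchoring.
  std::vector<uint8_t> anchor(n, 0);
  if (anchor_delta >= 0) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          size_t i = (size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z);
          if (!img[i]) continue;
          bool is_anchor = true;
          for (int dz = -1; dz <= 1 && is_anchor; ++dz)
            for (int dy = -1; dy <= 1 && is_anchor; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (dx == 0 && dy == 0 && dz == 0) continue;
                int qx = x + dx, qy = y + dy, qz = z + dz;
                if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz) continue;
                size_t q = (size_t)qx + (size_t)nx * ((size_t)qy + (size_t)ny * qz);
                if (dist[q] > dist[i] + anchor_delta) { is_anchor = false; break; }
              }
          anchor[i] = is_anchor ? 1 : 0;
        }
  }

  // min-heap on (distance, linear index): index ties make the order
  // fully deterministic
  typedef std::pair<double, size_t> Item;
  std::priority_queue<Item, std::vector<Item>, std::greater<Item> > heap;

  bool cube[27];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t i = (size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z);
        if (!img[i]) continue;
        neighbourhood(g, x, y, z, cube);
        if (n_fg_neighbours(cube) < 26)  // touches background: border voxel
          heap.push(Item(dist[i], i));
      }

  while (!heap.empty()) {
    size_t i = heap.top().second;
    heap.pop();
    if (!img[i] || anchor[i]) continue;
    int x = (int)(i % nx);
    int y = (int)((i / nx) % ny);
    int z = (int)(i / ((size_t)nx * ny));
    neighbourhood(g, x, y, z, cube);
    if (n_fg_neighbours(cube) <= 1) continue;  // curve endpoint / isolated
    if (!is_simple(cube)) continue;
    img[i] = 0;
    // deletion may render neighbours simple: requeue them
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          int qx = x + dx, qy = y + dy, qz = z + dz;
          if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz) continue;
          size_t q = (size_t)qx + (size_t)nx * ((size_t)qy + (size_t)ny * qz);
          if (img[q]) heap.push(Item(dist[q], q));
        }
  }

  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = img[i] != 0;
  return out;
}
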