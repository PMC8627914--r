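#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Capsule rasterization: a voxel is foreground iff its center lies within
// radius r of the centerline segment.  Ends may be cut flat (occlusion
// faces), in which case points projecting beyond the cut plane are excluded.

// segs columns: x1 y1 z1 x2 y2 z2 r flat_start flat_end
// [[Rcpp::export]]
LogicalVector cpp_rasterize_capsules(IntegerVector dims, NumericVector origin,
                                     NumericVector spacing, NumericMatrix segs) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);

  for (int s = 0; s < segs.nrow(); ++s) {
    const double ax = segs(s, 0), ay = segs(s, 1), az = segs(s, 2);
    const double bx = segs(s, 3), by = segs(s, 4), bz = segs(s, 5);
    const double r = segs(s, 6);
    const bool flat_a = segs(s, 7) > 0.5, flat_b = segs(s, 8) > 0.5;
    const double vx = bx - ax, vy = by - ay, vz = bz - az;
    const double vv = vx * vx + vy * vy + vz * vz;

    const double lo[3] = {std::min(ax, bx) - r, std::min(ay, by) - r, std::min(az, bz) - r};
    const double hi[3] = {std::max(ax, bx) + r, std::max(ay, by) + r, std::max(az, bz) + r};
    int i0[3], i1[3];
    for (int a = 0; a < 3; ++a) {
      i0[a] = std::max(0, (int)std::floor((lo[a] - origin[a]) / spacing[a]));
      int nmax = (a == 0 ? nx : (a == 1 ? ny : nz)) - 1;
      i1[a] = std::min(nmax, (int)std::ceil((hi[a] - origin[a]) / spacing[a]));
    }

    for (int k = i0[2]; k <= i1[2]; ++k) {
      const double pz = origin[2] + k * spacing[2];
      for (int j = i0[1]; j <= i1[1]; ++j) {
        const double py = origin[1] + j * spacing[1];
        for (int i = i0[0]; i <= i1[0]; ++i) {
          const double px = origin[0] + i * spacing[0];
          double t = 0.0;
          if (vv > 0.0)
            t = ((px - ax) * vx + (py - ay) * vy + (pz - az) * vz) / vv;
          if (flat_a && t < 0.0) continue;
          if (flat_b && t > 1.0) continue;
          const double tc = std::max(0.0, std::min(1.0, t));
          const double cx = ax + tc * vx, cy = ay + tc * vy, cz = az + tc * vz;
          const double dx = px - cx, dy = py - cy, dz = pz - cz;
          if (dx * dx + dy * dy + dz * dz <= r * r + 1e-12)
            out[(R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k)] = true;
        }
      }
    }
  }
  return out;
}
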