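#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Exact Euclidean distance transform (squared-distance lower-envelope
// algorithm, separable per axis) with anisotropic voxel spacing.
// Distances are from each foreground voxel center to the nearest
// background voxel center, in physical units.

namespace {

const double BIG = 1e20;  // finite "unset" value: differences stay exact
const double INF = std::numeric_limits<double>::infinity();

// One-dimensional squared distance transform with weight w2 = spacing^2.
void dt1d(const double* f, double* d, int n, double w2) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;   // true infinities: intersection values can exceed 1e20
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      double num = (f[q] + w2 * q * q) - (f[p] + w2 * p * p);
      double den = 2.0 * w2 * (q - p);
      s = num / den;
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = w2 * (q - p) * (q - p) + f[p];
  }
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<double> f(n);
  for (size_t i = 0; i < n; ++i) f[i] = mask[i] ? BIG : 0.0;

  std::vector<double> line, out;

  // x axis
  line.resize(nx); out.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      size_t base = (size_t)nx * ((size_t)y + (size_t)ny * z);
      for (int x = 0; x < nx; ++x) line[x] = f[base + x];
      dt1d(line.data(), out.data(), nx, spacing[0] * spacing[0]);
      for (int x = 0; x < nx; ++x) f[base + x] = out[x];
    }
  // y axis
  line.resize(ny); out.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) line[y] = f[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z)];
      dt1d(line.data(), out.data(), ny, spacing[1] * spacing[1]);
      for (int y = 0; y < ny; ++y) f[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z)] = out[y];
    }
  // z axis
  line.resize(nz); out.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) line[z] = f[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z)];
      dt1d(line.data(), out.data(), nz, spacing[2] * spacing[2]);
      for (int z = 0; z < nz; ++z) f[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z)] = out[z];
    }

  NumericVector res(n);
  for (size_t i = 0; i < n; ++i) res[i] = mask[i] ? std::sqrt(f[i]) : 0.0;
  return res;
}
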