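#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Felzenszwalb & Huttenlocher separable squared Euclidean distance transform.
// One 1D pass along a line; `w` is the physical sample spacing on that line.
static void dt1d(std::vector<double>& f, double w) {
  const int n = (int)f.size();
  if (n == 0) return;
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) ++k;
    double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
  f = d;
}

// Squared EDT of a 2D or 3D logical target mask with per-axis spacing
// (physical units). Returns, for every pixel, the squared distance to the
// nearest TRUE pixel (pixel-center to pixel-center). Dims are (y, x[, z]).
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector target, IntegerVector dims,
                     NumericVector spacing) {
  const int nd = dims.size();
  if (nd != 2 && nd != 3)
    stop("distance transform supports 2D or 3D arrays");
  const int ny = dims[0], nx = dims[1], nz = (nd == 3) ? dims[2] : 1;
  // large finite sentinel: infinity breaks the lower-envelope updates
  // (INF - INF = NaN), 1e30 does not overflow when squared distances add
  const double INF = 1e30;
  R_xlen_t ntot = (R_xlen_t)ny * nx * nz;
  NumericVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i)
    out[i] = target[i] ? 0.0 : INF;

  std::vector<double> line;

  // pass along y (fastest-varying index)
  line.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t off = (R_xlen_t)z * ny * nx + (R_xlen_t)x * ny;
      for (int y = 0; y < ny; ++y) line[y] = out[off + y];
      dt1d(line, spacing[0]);
      for (int y = 0; y < ny; ++y) out[off + y] = line[y];
    }
  // pass along x
  line.assign(nx, 0.0);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * ny * nx + y;
      for (int x = 0; x < nx; ++x) line[x] = out[base + (R_xlen_t)x * ny];
      dt1d(line, spacing[1]);
      for (int x = 0; x < nx; ++x) out[base + (R_xlen_t)x * ny] = line[x];
    }
  // pass along z
  if (nd == 3) {
    line.assign(nz, 0.0);
    R_xlen_t plane = (R_xlen_t)ny * nx;
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        R_xlen_t base = (R_xlen_t)x * ny + y;
        for (int z = 0; z < nz; ++z) line[z] = out[base + (R_xlen_t)z * plane];
        dt1d(line, spacing[2]);
        for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * plane] = line[z];
      }
  }
  return out;
}

// Connected-component labeling, 8-connectivity in 2D / 26 in 3D,
// iterative flood fill. Dims are (y, x[, z]); returns integer labels 1..N.
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, IntegerVector dims) {
  const int nd = dims.size();
  if (nd != 2 && nd != 3)
    stop("labeling supports 2D or 3D arrays");
  const int ny = dims[0], nx = dims[1], nz = (nd == 3) ? dims[2] : 1;
  const R_xlen_t plane = (R_xlen_t)ny * nx;
  R_xlen_t ntot = plane * nz;
  IntegerVector lab(ntot);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < ntot; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int z = (int)(p / plane);
      int rem = (int)(p % plane);
      int x = rem / ny, y = rem % ny;
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          int xx = x + dx;
          if (xx < 0 || xx >= nx) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            int yy = y + dy;
            if (yy < 0 || yy >= ny) continue;
            if (dx == 0 && dy == 0 && dz == 0) continue;
            R_xlen_t q = (R_xlen_t)zz * plane + (R_xlen_t)xx * ny + yy;
            if (mask[q] && lab[q] == 0) {
              lab[q] = next;
              stack.push_back(q);
            }
          }
        }
      }
    }
  }
  return lab;
}
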