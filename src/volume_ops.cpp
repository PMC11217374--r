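#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>

using namespace Rcpp;

// Reflect an out-of-range index back into [0, n-1] (mirror boundary,
// whole-sample reflection; adequate for kernels shorter than the axis).
static inline int reflect_index(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Convolve one axis of a 3D array with a 1D kernel (mirror boundary).
// axis: 0 = x (fastest-varying), 1 = y, 2 = z.
static void convolve_axis(std::vector<double> &a, int nx, int ny, int nz,
                          const NumericVector &kernel, int axis) {
  const int k = kernel.size();
  const int r = (k - 1) / 2;
  const int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  const R_xlen_t stride = (axis == 0) ? 1
                        : (axis == 1) ? (R_xlen_t)nx
                        : (R_xlen_t)nx * ny;
  std::vector<double> line(n);

  const int n_outer1 = (axis == 0) ? ny : nx;
  const int n_outer2 = (axis == 2) ? ny : nz;
  for (int o2 = 0; o2 < n_outer2; ++o2) {
    for (int o1 = 0; o1 < n_outer1; ++o1) {
      R_xlen_t base;
      if (axis == 0)      base = (R_xlen_t)o1 * nx + (R_xlen_t)o2 * nx * ny;
      else if (axis == 1) base = (R_xlen_t)o1 + (R_xlen_t)o2 * nx * ny;
      else                base = (R_xlen_t)o1 + (R_xlen_t)o2 * nx;
      for (int i = 0; i < n; ++i) line[i] = a[base + stride * i];
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int j = 0; j < k; ++j) {
          int src = reflect_index(i + j - r, n);
          acc += line[src] * kernel[j];
        }
        a[base + stride * i] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_convolve_separable(NumericVector data, IntegerVector dims,
                                     NumericVector kx, NumericVector ky,
                                     NumericVector kz) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> a(data.begin(), data.end());
  if (kx.size() > 1) convolve_axis(a, nx, ny, nz, kx, 0);
  if (ky.size() > 1) convolve_axis(a, nx, ny, nz, ky, 1);
  if (kz.size() > 1) convolve_axis(a, nx, ny, nz, kz, 2);
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}

// Label connected components of a 3D foreground mask.
// connectivity: 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).
// Returns integer labels (0 = background), flattened in R array order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(ntot, 0);

  // neighbour offsets
  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        int nzero = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (nzero == 0) continue;
        if (connectivity == 6 && nzero > 1) continue;
        if (connectivity == 18 && nzero > 2) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
  const int nnb = dx.size();

  int current = 0;
  std::vector<R_xlen_t> queue;
  for (R_xlen_t s = 0; s < ntot; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++current;
    labels[s] = current;
    queue.clear();
    queue.push_back(s);
    while (!queue.empty()) {
      R_xlen_t v = queue.back();
      queue.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (int j = 0; j < nnb; ++j) {
        int xx = x + dx[j], yy = y + dy[j], zz = z + dz[j];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)xx + (R_xlen_t)yy * nx + (R_xlen_t)zz * nx * ny;
        if (mask[w] && labels[w] == 0) {
          labels[w] = current;
          queue.push_back(w);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
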