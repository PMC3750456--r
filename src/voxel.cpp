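#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Seeded 6-connected flood fill over the complement of `blocked`.
// Stops early (leaked = true) once the fill exceeds max_voxels.
// [[Rcpp::export(name = ".flood_fill6")]]
List flood_fill6(LogicalVector blocked, IntegerVector dims, IntegerVector seed,
                 double max_voxels) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (blocked.size() != n) stop("blocked mask does not match dims");
  int si = seed[0] - 1, sj = seed[1] - 1, sk = seed[2] - 1;
  if (si < 0 || sj < 0 || sk < 0 || si >= nx || sj >= ny || sk >= nz)
    stop("seed outside volume");
  LogicalVector out(n, false);
  const int s0 = lin(si, sj, sk, nx, ny);
  if (blocked[s0]) stop("seed voxel is blocked (inside bone or stop region)");
  std::vector<int> queue;
  queue.reserve(1 << 16);
  queue.push_back(s0);
  out[s0] = true;
  double count = 1.0;
  bool leaked = false;
  size_t head = 0;
  while (head < queue.size()) {
    const int cur = queue[head++];
    const int k = cur / (nx * ny);
    const int rem = cur - k * nx * ny;
    const int j = rem / nx;
    const int i = rem - j * nx;
    const int di[6] = {-1, 1, 0, 0, 0, 0};
    const int dj[6] = {0, 0, -1, 1, 0, 0};
    const int dk[6] = {0, 0, 0, 0, -1, 1};
    for (int d = 0; d < 6; ++d) {
      const int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      const int q = lin(ii, jj, kk, nx, ny);
      if (out[q] || blocked[q]) continue;
      out[q] = true;
      queue.push_back(q);
      count += 1.0;
      if (count > max_voxels) { leaked = true; break; }
    }
    if (leaked) break;
  }
  return List::create(_["mask"] = out, _["count"] = count, _["leaked"] = leaked);
}

// Binary dilation by an arbitrary offset set (rows of `offsets`, voxel units).
// [[Rcpp::export(name = ".binary_dilate")]]
LogicalVector binary_dilate(LogicalVector mask, IntegerVector dims,
                            IntegerMatrix offsets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask does not match dims");
  LogicalVector out(n, false);
  const int no = offsets.nrow();
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const int q = lin(i, j, k, nx, ny);
        if (!mask[q]) continue;
        for (int o = 0; o < no; ++o) {
          const int ii = i + offsets(o, 0), jj = j + offsets(o, 1), kk = k + offsets(o, 2);
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
          out[lin(ii, jj, kk, nx, ny)] = true;
        }
      }
    }
  }
  return out;
}

// Separable Gaussian smoothing, sigma per axis in voxel units (0 = skip axis).
// [[Rcpp::export(name = ".gauss_smooth3")]]
NumericVector gauss_smooth3(NumericVector arr, IntegerVector dims,
                            NumericVector sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (arr.size() != n) stop("array does not match dims");
  std::vector<double> a(arr.begin(), arr.end()), b(n);
  const int nd[3] = {nx, ny, nz};
  const int stride[3] = {1, nx, nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma[ax];
    if (s <= 0) continue;
    const int r = (int)std::ceil(3.0 * s);
    std::vector<double> w(2 * r + 1);
    double wsum = 0;
    for (int t = -r; t <= r; ++t) { w[t + r] = std::exp(-0.5 * t * t / (s * s)); wsum += w[t + r]; }
    for (double &x : w) x /= wsum;
    const int len = nd[ax], st = stride[ax];
    // iterate over all lines along axis ax
    const int n1 = (ax == 0) ? ny : nx;
    const int n2 = (ax == 2) ? ny : nz;
    const int st1 = (ax == 0) ? nx : 1;
    const int st2 = (ax == 2) ? nx : nx * ny;
    for (int v = 0; v < n2; ++v) {
      for (int u = 0; u < n1; ++u) {
        const R_xlen_t base = (R_xlen_t)u * st1 + (R_xlen_t)v * st2;
        for (int p = 0; p < len; ++p) {
          double acc = 0;
          for (int t = -r; t <= r; ++t) {
            int pp = p + t;
            if (pp < 0) pp = 0; else if (pp >= len) pp = len - 1;  // replicate border
            acc += w[t + r] * a[base + (R_xlen_t)pp * st];
          }
          b[base + (R_xlen_t)p * st] = acc;
        }
      }
    }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}
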