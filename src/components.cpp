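#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// 3D connected components on (z, y, x) arrays stored column-major with z
// fastest (R's native layout for dim = c(nz, ny, nx)). Foreground is
// strictly `intensity > threshold`; ties go to background.

static std::vector<std::array<int, 3>> neighbor_offsets(int connectivity) {
  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manh != 1) continue;
        nb.push_back({dz, dy, dx});
      }
  return nb;
}

// Label all components of {voxel : img[voxel] > threshold}. Background 0,
// components numbered 1..k in scan order. `dims` = (nz, ny, nx).
// [[Rcpp::export]]
IntegerVector cc_label3d(NumericVector img, IntegerVector dims,
                         double threshold, int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector labels(n, 0);
  std::vector<std::array<int, 3>> nb = neighbor_offsets(connectivity);
  std::vector<int> stack;
  int lab = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!(img[i] > threshold) || labels[i] != 0) continue;
    ++lab;
    labels[i] = lab;
    stack.push_back((int)i);
    while (!stack.empty()) {
      int j = stack.back();
      stack.pop_back();
      int jz = j % nz, rest = j / nz;
      int jy = rest % ny, jx = rest / ny;
      for (const auto &d : nb) {
        int zz = jz + d[0], yy = jy + d[1], xx = jx + d[2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        int k = zz + nz * (yy + ny * xx);
        if (img[k] > threshold && labels[k] == 0) {
          labels[k] = lab;
          stack.push_back(k);
        }
      }
    }
  }
  return labels;
}

// Volume-filtered component counts at each threshold level. Voxel indices
// are pre-sorted by descending intensity so level t only visits its own
// foreground (a prefix of the order); a per-level stamp replaces mask
// reallocation. Component counted iff min_vol <= size <= max_vol.
// [[Rcpp::export]]
IntegerVector cc_count_curve(NumericVector img, IntegerVector dims,
                             NumericVector thresholds, int connectivity,
                             int min_vol, double max_vol) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<std::array<int, 3>> nb = neighbor_offsets(connectivity);
  std::vector<int> order(n);
  std::iota(order.begin(), order.end(), 0);
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return img[a] > img[b]; });
  std::vector<int> seen(n, -1);
  std::vector<int> stack;
  const int nt = thresholds.size();
  IntegerVector counts(nt);
  for (int ti = 0; ti < nt; ++ti) {
    const double t = thresholds[ti];
    int cnt = 0;
    for (R_xlen_t oi = 0; oi < n; ++oi) {
      int i = order[oi];
      if (!(img[i] > t)) break;  // rest of the order is background here
      if (seen[i] == ti) continue;
      int size = 0;
      seen[i] = ti;
      stack.push_back(i);
      while (!stack.empty()) {
        int j = stack.back();
        stack.pop_back();
        ++size;
        int jz = j % nz, rest = j / nz;
        int jy = rest % ny, jx = rest / ny;
        for (const auto &d : nb) {
          int zz = jz + d[0], yy = jy + d[1], xx = jx + d[2];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          int k = zz + nz * (yy + ny * xx);
          if (img[k] > t && seen[k] != ti) {
            seen[k] = ti;
            stack.push_back(k);
          }
        }
      }
      if (size >= min_vol && size <= max_vol) ++cnt;
    }
    counts[ti] = cnt;
  }
  return counts;
}
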