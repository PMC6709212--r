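// Threshold-free cluster enhancement and 3-D connected-component labelling.

#include <Rcpp.h>
#include <array>
#include <algorithm>
using namespace Rcpp;

// neighbour offsets for 6 / 18 / 26 connectivity on a 3-D grid
static void neighbour_offsets(int connectivity,
                              std::vector<std::array<int, 3>>& off) {
  off.clear();
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off.push_back({dx, dy, dz});
      }
}

// label connected components of a binary mask; labels start at 1, 0 = background
static int label_mask(const std::vector<char>& mask, int nx, int ny, int nz,
                      int connectivity, std::vector<int>& labels) {
  std::vector<std::array<int, 3>> off;
  neighbour_offsets(connectivity, off);
  const int nvox = nx * ny * nz;
  labels.assign(nvox, 0);
  int next = 0;
  std::vector<int> stack;
  for (int v = 0; v < nvox; ++v) {
    if (!mask[v] || labels[v]) continue;
    ++next;
    labels[v] = next;
    stack.clear();
    stack.push_back(v);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int x = cur % nx, y = (cur / nx) % ny, zc = cur / (nx * ny);
      for (const auto& o : off) {
        int X = x + o[0], Y = y + o[1], Z = zc + o[2];
        if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
        int w = X + nx * (Y + ny * Z);
        if (mask[w] && !labels[w]) {
          labels[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  return next;
}

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(NumericVector map, IntegerVector dims,
                                   double threshold, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nvox = nx * ny * nz;
  if (map.size() != nvox) stop("map length does not match dims");
  std::vector<char> mask(nvox);
  for (int v = 0; v < nvox; ++v)
    mask[v] = (!NumericVector::is_na(map[v]) && map[v] >= threshold) ? 1 : 0;
  std::vector<int> labels;
  label_mask(mask, nx, ny, nz, connectivity, labels);
  IntegerVector out(nvox);
  std::copy(labels.begin(), labels.end(), out.begin());
  return out;
}

// TFCE of a non-negative map: for each voxel, sum over thresholds
// h = step, 2*step, ... of extent(h)^E * h^H * step, extent(h) being the size
// of the suprathreshold (>= h) component containing the voxel.
//
// Computed by descending through the thresholds once, activating voxels in
// decreasing order of height and merging components with union-find; per
// threshold the contribution size^E * h^H * step is added to every active
// voxel. Equivalent to relabelling at every threshold, but the work per
// threshold is proportional to the suprathreshold extent only.

static int uf_find(std::vector<int>& parent, int v) {
  while (parent[v] != v) {
    parent[v] = parent[parent[v]];
    v = parent[v];
  }
  return v;
}

// [[Rcpp::export(name = ".cpp_tfce")]]
NumericVector cpp_tfce(NumericVector map, IntegerVector dims, double H,
                       double E, double step, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nvox = nx * ny * nz;
  if (map.size() != nvox) stop("map length does not match dims");
  NumericVector out(nvox);
  double mx = 0.0;
  for (int v = 0; v < nvox; ++v)
    if (std::isfinite(map[v]) && map[v] > mx) mx = map[v];
  if (mx <= 0.0) return out;
  int n_steps = (int)std::floor(mx / step + 1e-12);
  if (n_steps < 1) return out;

  std::vector<std::array<int, 3>> off;
  neighbour_offsets(connectivity, off);

  // voxels with positive value, sorted by decreasing height
  std::vector<int> order;
  order.reserve(nvox);
  for (int v = 0; v < nvox; ++v)
    if (std::isfinite(map[v]) && map[v] > 0.0) order.push_back(v);
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return map[a] > map[b]; });

  std::vector<int> parent(nvox), csize(nvox, 0);
  std::vector<char> active(nvox, 0);
  size_t p = 0;
  for (int s = n_steps; s >= 1; --s) {
    double h = s * step;
    double hterm = std::pow(h, H) * step;
    while (p < order.size() && map[order[p]] >= h) {
      int v = order[p++];
      parent[v] = v;
      csize[v] = 1;
      active[v] = 1;
      int x = v % nx, y = (v / nx) % ny, zc = v / (nx * ny);
      for (const auto& o : off) {
        int X = x + o[0], Y = y + o[1], Z = zc + o[2];
        if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
        int w = X + nx * (Y + ny * Z);
        if (!active[w]) continue;
        int rv = uf_find(parent, v), rw = uf_find(parent, w);
        if (rv != rw) {
          if (csize[rv] < csize[rw]) std::swap(rv, rw);
          parent[rw] = rv;
          csize[rv] += csize[rw];
        }
      }
    }
    for (size_t i = 0; i < p; ++i) {
      int v = order[i];
      int r = uf_find(parent, v);
      double ext = (double)csize[r];
      double eterm = (E == 0.5) ? std::sqrt(ext) : std::pow(ext, E);
      out[v] += eterm * hterm;
    }
  }
  return out;
}
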