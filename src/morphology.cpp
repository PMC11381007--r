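#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// 3-D binary image utilities used by the lung segmentation stage.
// All functions take a logical array with a dim attribute of length 3 and
// treat it in the storage (column-major) order; connectivity is
// face-adjacency (6-connected), the usual choice for CT masks.

static inline int idx3(int i, int j, int k, int ni, int nj) {
  return i + ni * (j + (long long)nj * k);
}

// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(LogicalVector mask) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("mask must be a 3-D array");
  const int ni = dims[0], nj = dims[1], nk = dims[2];
  const R_xlen_t n = mask.size();
  IntegerVector labels(n, 0);
  labels.attr("dim") = dims;
  int current = 0;
  std::vector<int> queue_buf;
  queue_buf.reserve(1024);
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++current;
    queue_buf.clear();
    queue_buf.push_back((int)start);
    labels[start] = current;
    size_t head = 0;
    while (head < queue_buf.size()) {
      int v = queue_buf[head++];
      int i = v % ni;
      int rest = v / ni;
      int j = rest % nj;
      int k = rest / nj;
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int t = 0; t < 6; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || ii >= ni || jj < 0 || jj >= nj || kk < 0 || kk >= nk)
          continue;
        int w = idx3(ii, jj, kk, ni, nj);
        if (mask[w] && labels[w] == 0) {
          labels[w] = current;
          queue_buf.push_back(w);
        }
      }
    }
  }
  labels.attr("n_components") = current;
  return labels;
}

// Dilation by an arbitrary structuring element given as a matrix of integer
// voxel offsets (rows = offsets, columns = the three axes).
// [[Rcpp::export(name = ".binary_dilate3d")]]
LogicalVector binary_dilate3d(LogicalVector mask, IntegerMatrix offsets) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("mask must be a 3-D array");
  const int ni = dims[0], nj = dims[1], nk = dims[2];
  const R_xlen_t n = mask.size();
  LogicalVector out(n, false);
  out.attr("dim") = dims;
  const int m = offsets.nrow();
  for (R_xlen_t v = 0; v < n; ++v) {
    if (!mask[v]) continue;
    int i = v % ni;
    int rest = v / ni;
    int j = rest % nj;
    int k = rest / nj;
    for (int t = 0; t < m; ++t) {
      int ii = i + offsets(t, 0), jj = j + offsets(t, 1), kk = k + offsets(t, 2);
      if (ii < 0 || ii >= ni || jj < 0 || jj >= nj || kk < 0 || kk >= nk)
        continue;
      out[idx3(ii, jj, kk, ni, nj)] = true;
    }
  }
  return out;
}

// Erosion: a voxel survives if every offset lands on foreground. Offsets
// falling outside the grid are treated as foreground so that the border does
// not erode structures purely by image-edge effects.
// [[Rcpp::export(name = ".binary_erode3d")]]
LogicalVector binary_erode3d(LogicalVector mask, IntegerMatrix offsets) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("mask must be a 3-D array");
  const int ni = dims[0], nj = dims[1], nk = dims[2];
  const R_xlen_t n = mask.size();
  LogicalVector out(n, false);
  out.attr("dim") = dims;
  const int m = offsets.nrow();
  for (R_xlen_t v = 0; v < n; ++v) {
    if (!mask[v]) continue;
    int i = v % ni;
    int rest = v / ni;
    int j = rest % nj;
    int k = rest / nj;
    bool keep = true;
    for (int t = 0; t < m && keep; ++t) {
      int ii = i + offsets(t, 0), jj = j + offsets(t, 1), kk = k + offsets(t, 2);
      if (ii < 0 || ii >= ni || jj < 0 || jj >= nj || kk < 0 || kk >= nk)
        continue;
      if (!mask[idx3(ii, jj, kk, ni, nj)]) keep = false;
    }
    out[v] = keep;
  }
  return out;
}
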