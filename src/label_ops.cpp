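// Binary-image utilities used by the background mask: 3D connected
// components (6-connectivity) and per-slice hole filling.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".cc_label3")]]
IntegerVector cc_label3(LogicalVector mask, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const R_xlen_t N = (R_xlen_t)X * Y * Z;
  IntegerVector lab(N);
  lab.attr("dim") = dims;
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < N; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      const int x = v % X, y = (v / X) % Y, z = v / ((R_xlen_t)X * Y);
      const int nx[6] = {x - 1, x + 1, x, x, x, x};
      const int ny[6] = {y, y, y - 1, y + 1, y, y};
      const int nz[6] = {z, z, z, z, z - 1, z + 1};
      for (int j = 0; j < 6; ++j) {
        if (nx[j] < 0 || nx[j] >= X || ny[j] < 0 || ny[j] >= Y ||
            nz[j] < 0 || nz[j] >= Z) continue;
        const R_xlen_t w = nx[j] + (R_xlen_t)X * (ny[j] + (R_xlen_t)Y * nz[j]);
        if (mask[w] && !lab[w]) { lab[w] = cur; stack.push_back(w); }
      }
    }
  }
  lab.attr("n") = cur;
  return lab;
}

// Fill holes slice-by-slice (along the third axis): background pixels not
// reachable from the slice border become foreground.
// [[Rcpp::export(name = ".fill_holes_slices")]]
LogicalVector fill_holes_slices(LogicalVector mask, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  LogicalVector out(clone(mask));
  out.attr("dim") = dims;
  std::vector<char> reach((size_t)X * Y);
  std::vector<int> stack;
  for (int z = 0; z < Z; ++z) {
    const R_xlen_t off = (R_xlen_t)X * Y * z;
    std::fill(reach.begin(), reach.end(), 0);
    stack.clear();
    for (int x = 0; x < X; ++x)
      for (int y = 0; y < Y; ++y) {
        if (x != 0 && x != X - 1 && y != 0 && y != Y - 1) continue;
        const int p = x + X * y;
        if (!mask[off + p] && !reach[p]) { reach[p] = 1; stack.push_back(p); }
      }
    while (!stack.empty()) {
      const int v = stack.back(); stack.pop_back();
      const int x = v % X, y = v / X;
      const int nx[4] = {x - 1, x + 1, x, x};
      const int ny[4] = {y, y, y - 1, y + 1};
      for (int j = 0; j < 4; ++j) {
        if (nx[j] < 0 || nx[j] >= X || ny[j] < 0 || ny[j] >= Y) continue;
        const int w = nx[j] + X * ny[j];
        if (!mask[off + w] && !reach[w]) { reach[w] = 1; stack.push_back(w); }
      }
    }
    for (int p = 0; p < X * Y; ++p)
      if (!mask[off + p] && !reach[p]) out[off + p] = TRUE;
  }
  return out;
}
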