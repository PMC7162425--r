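#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Fixed-radius neighbour search by uniform grid hashing (cell size = r).
// Distances are compared with <= r, so boundary ties are included.

static inline int64_t cell_key(int cx, int cy, int cz) {
  // pack three 21-bit signed cell indices into one 64-bit key
  const int64_t off = 1 << 20;
  return (((int64_t)(cx + off)) << 42) | (((int64_t)(cy + off)) << 21) |
         (int64_t)(cz + off);
}

// [[Rcpp::export(rng = false)]]
List radius_neighbors_cpp(NumericMatrix coords, double r) {
  const int n = coords.nrow();
  const int d = coords.ncol();
  std::unordered_map<int64_t, std::vector<int> > grid;
  grid.reserve(n * 2);
  std::vector<int> cx(n), cy(n), cz(n, 0);
  for (int i = 0; i < n; ++i) {
    cx[i] = (int)std::floor(coords(i, 0) / r);
    cy[i] = (int)std::floor(coords(i, 1) / r);
    if (d > 2) cz[i] = (int)std::floor(coords(i, 2) / r);
    grid[cell_key(cx[i], cy[i], cz[i])].push_back(i);
  }
  const double r2 = r * r;
  List out(n);
  std::vector<int> buf;
  for (int i = 0; i < n; ++i) {
    buf.clear();
    const int zlo = (d > 2) ? cz[i] - 1 : 0, zhi = (d > 2) ? cz[i] + 1 : 0;
    for (int ax = cx[i] - 1; ax <= cx[i] + 1; ++ax)
      for (int ay = cy[i] - 1; ay <= cy[i] + 1; ++ay)
        for (int az = zlo; az <= zhi; ++az) {
          std::unordered_map<int64_t, std::vector<int> >::const_iterator it =
            grid.find(cell_key(ax, ay, az));
          if (it == grid.end()) continue;
          const std::vector<int>& cell = it->second;
          for (size_t k = 0; k < cell.size(); ++k) {
            const int j = cell[k];
            if (j == i) continue;
            double s = 0.0;
            for (int c = 0; c < d; ++c) {
              const double dx = coords(i, c) - coords(j, c);
              s += dx * dx;
            }
            if (s <= r2) buf.push_back(j + 1);  // 1-based for R
          }
        }
    std::sort(buf.begin(), buf.end());
    out[i] = IntegerVector(buf.begin(), buf.end());
  }
  return out;
}
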