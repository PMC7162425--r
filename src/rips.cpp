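#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstring>
#include <cstdint>
using namespace Rcpp;

// Persistent homology of a Rips filtration by boundary-matrix reduction over
// GF(2). The scale parameter is the pairwise-distance (edge-length)
// threshold: a simplex enters the filtration at the length of its longest
// edge. H0 is paired by a union-find pass over the sorted edges; higher
// homology (H1, and H2 when tetrahedra are requested) uses column reduction
// in decreasing dimension with the clearing optimization and dense bit-packed
// column accumulation for speed. Zero-persistence pairs are dropped; features
// alive at max_scale are reported with death = Inf.

namespace {

struct Simplex {
  int v[4];
  double filt;
};

struct UF2 {
  std::vector<int> parent;
  explicit UF2(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
};

inline bool simplex_less(const Simplex& a, const Simplex& b, int nv) {
  if (a.filt != b.filt) return a.filt < b.filt;
  for (int k = 0; k < nv; ++k)
    if (a.v[k] != b.v[k]) return a.v[k] < b.v[k];
  return false;
}

// Dense GF(2) column accumulator over `nrow` rows.
class BitCol {
  std::vector<uint64_t> w;
 public:
  explicit BitCol(int nrow) : w((nrow + 63) / 64, 0ull) {}
  void clear() { std::fill(w.begin(), w.end(), 0ull); }
  void set(const std::vector<int>& idx) {
    for (size_t k = 0; k < idx.size(); ++k) w[idx[k] >> 6] ^= (1ull << (idx[k] & 63));
  }
  void xor_in(const std::vector<int>& idx) { set(idx); }
  int pivot(int hint) const {  // highest set bit <= hint, or -1
    int word = hint >> 6;
    uint64_t cur = w[word] & ((hint & 63) == 63 ? ~0ull : ((1ull << ((hint & 63) + 1)) - 1));
    while (true) {
      if (cur) return (word << 6) + 63 - __builtin_clzll(cur);
      if (--word < 0) return -1;
      cur = w[word];
    }
  }
  void extract(std::vector<int>& out) const {
    out.clear();
    for (size_t i = 0; i < w.size(); ++i) {
      uint64_t cur = w[i];
      while (cur) {
        const int b = __builtin_ctzll(cur);
        out.push_back((int)(i << 6) + b);
        cur &= cur - 1;
      }
    }
  }
};

// Reduce columns of dimension p (boundaries given as sorted row-index
// vectors) against rows of dimension p-1. Returns for each column its final
// pivot row (-1 if the column reduced to zero). `pairs_out` receives
// (row, col) persistence pairs.
void reduce_dim(const std::vector<std::vector<int> >& boundary,
                const std::vector<bool>& skip,  // cleared columns
                int nrow,
                std::vector<int>& pivot_of_row,
                std::vector<char>& col_zero) {
  const int ncol = (int)boundary.size();
  pivot_of_row.assign(nrow, -1);
  col_zero.assign(ncol, 0);
  std::vector<std::vector<int> > stored(ncol);
  BitCol acc(nrow);
  std::vector<int> tmp;
  for (int c = 0; c < ncol; ++c) {
    if (skip.size() && skip[c]) { col_zero[c] = 1; continue; }
    const std::vector<int>& bd = boundary[c];
    int piv = bd.back();
    if (pivot_of_row[piv] < 0) {  // apparent/easy pair: claim directly
      pivot_of_row[piv] = c;
      stored[c] = bd;
      continue;
    }
    acc.clear();
    acc.set(bd);
    while (true) {
      piv = acc.pivot(piv);
      if (piv < 0) { col_zero[c] = 1; break; }
      const int owner = pivot_of_row[piv];
      if (owner < 0) {
        pivot_of_row[piv] = c;
        acc.extract(tmp);
        stored[c] = tmp;
        break;
      }
      acc.xor_in(stored[owner]);
    }
  }
}

}  // namespace

// [[Rcpp::export(rng = false)]]
NumericMatrix rips_persistence_cpp(NumericMatrix pts, double max_scale,
                                   int max_simplex_dim) {
  const int n = pts.nrow();
  const int d = pts.ncol();
  std::vector<double> dist((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double dx = pts(i, c) - pts(j, c);
        s += dx * dx;
      }
      const double dd = std::sqrt(s);
      dist[(size_t)i * n + j] = dd;
      dist[(size_t)j * n + i] = dd;
    }

  // -- edges --------------------------------------------------------------
  std::vector<Simplex> edges;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double dd = dist[(size_t)i * n + j];
      if (dd <= max_scale) {
        Simplex s; s.v[0] = i; s.v[1] = j; s.filt = dd;
        edges.push_back(s);
      }
    }
  std::sort(edges.begin(), edges.end(),
            [](const Simplex& a, const Simplex& b) { return simplex_less(a, b, 2); });
  const int ne = (int)edges.size();
  std::vector<int> edge_rank((size_t)n * n, -1);
  for (int e = 0; e < ne; ++e) {
    edge_rank[(size_t)edges[e].v[0] * n + edges[e].v[1]] = e;
    edge_rank[(size_t)edges[e].v[1] * n + edges[e].v[0]] = e;
  }

  std::vector<double> feat_dim, feat_birth, feat_death;
  // -- H0 by union-find ---------------------------------------------------
  UF2 uf(n);
  std::vector<bool> edge_positive(ne, false);  // creates a cycle
  for (int e = 0; e < ne; ++e) {
    const int a = uf.find(edges[e].v[0]), b = uf.find(edges[e].v[1]);
    if (a == b) { edge_positive[e] = true; continue; }
    uf.parent[a] = b;
    if (edges[e].filt > 0) {
      feat_dim.push_back(0); feat_birth.push_back(0); feat_death.push_back(edges[e].filt);
    }
  }
  int ncomp = 0;
  for (int i = 0; i < n; ++i) if (uf.find(i) == i) ++ncomp;
  for (int k = 0; k < ncomp; ++k) {
    feat_dim.push_back(0); feat_birth.push_back(0); feat_death.push_back(R_PosInf);
  }

  if (max_simplex_dim >= 2 && ne > 0) {
    // -- triangles --------------------------------------------------------
    std::vector<Simplex> tris;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        const double dij = dist[(size_t)i * n + j];
        if (dij > max_scale) continue;
        for (int k = j + 1; k < n; ++k) {
          const double dik = dist[(size_t)i * n + k], djk = dist[(size_t)j * n + k];
          if (dik > max_scale || djk > max_scale) continue;
          Simplex s; s.v[0] = i; s.v[1] = j; s.v[2] = k;
          s.filt = std::max(dij, std::max(dik, djk));
          tris.push_back(s);
        }
      }
    std::sort(tris.begin(), tris.end(),
              [](const Simplex& a, const Simplex& b) { return simplex_less(a, b, 3); });
    const int nt = (int)tris.size();

    std::vector<bool> tri_cleared(nt, false);
    std::vector<bool> tri_pivot_used(nt, false);
    if (max_simplex_dim >= 3 && nt > 0) {
      // -- tetrahedra, reduced first so triangle columns can be cleared ---
      std::vector<int64_t> tri_key(nt);
      for (int t = 0; t < nt; ++t)
        tri_key[t] = ((int64_t)tris[t].v[0] * n + tris[t].v[1]) * n + tris[t].v[2];
      std::vector<int> key_order(nt);
      for (int t = 0; t < nt; ++t) key_order[t] = t;
      std::sort(key_order.begin(), key_order.end(),
                [&](int a, int b) { return tri_key[a] < tri_key[b]; });
      std::vector<int64_t> keys_sorted(nt);
      for (int t = 0; t < nt; ++t) keys_sorted[t] = tri_key[key_order[t]];
      auto tri_rank = [&](int i, int j, int k) {
        const int64_t key = ((int64_t)i * n + j) * n + k;
        const int pos = (int)(std::lower_bound(keys_sorted.begin(), keys_sorted.end(), key)
                              - keys_sorted.begin());
        return key_order[pos];
      };
      std::vector<Simplex> tets;
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
          if (dist[(size_t)i * n + j] > max_scale) continue;
          for (int k = j + 1; k < n; ++k) {
            if (dist[(size_t)i * n + k] > max_scale ||
                dist[(size_t)j * n + k] > max_scale) continue;
            for (int l = k + 1; l < n; ++l) {
              const double d1 = dist[(size_t)i * n + l], d2 = dist[(size_t)j * n + l],
                           d3 = dist[(size_t)k * n + l];
              if (d1 > max_scale || d2 > max_scale || d3 > max_scale) continue;
              Simplex s; s.v[0] = i; s.v[1] = j; s.v[2] = k; s.v[3] = l;
              s.filt = std::max(std::max(dist[(size_t)i * n + j], dist[(size_t)i * n + k]),
                                std::max(std::max(dist[(size_t)j * n + k], d1),
                                         std::max(d2, d3)));
              tets.push_back(s);
            }
          }
        }
      std::sort(tets.begin(), tets.end(),
                [](const Simplex& a, const Simplex& b) { return simplex_less(a, b, 4); });
      std::vector<std::vector<int> > bnd(tets.size());
      for (size_t t = 0; t < tets.size(); ++t) {
        const int* v = tets[t].v;
        std::vector<int> b;
        b.push_back(tri_rank(v[1], v[2], v[3]));
        b.push_back(tri_rank(v[0], v[2], v[3]));
        b.push_back(tri_rank(v[0], v[1], v[3]));
        b.push_back(tri_rank(v[0], v[1], v[2]));
        std::sort(b.begin(), b.end());
        bnd[t] = b;
      }
      std::vector<int> pivot_of_tri;
      std::vector<char> tet_zero;
      reduce_dim(bnd, std::vector<bool>(), nt, pivot_of_tri, tet_zero);
      for (int tr = 0; tr < nt; ++tr) {
        const int c = pivot_of_tri[tr];
        if (c < 0) continue;
        tri_cleared[tr] = true;  // positive triangle, paired with a tet
        tri_pivot_used[tr] = true;
        if (tets[c].filt > tris[tr].filt) {
          feat_dim.push_back(2);
          feat_birth.push_back(tris[tr].filt);
          feat_death.push_back(tets[c].filt);
        }
      }
    }

    // -- triangle columns over edges (H1) ---------------------------------
    std::vector<std::vector<int> > bnd(nt);
    for (int t = 0; t < nt; ++t) {
      const int* v = tris[t].v;
      std::vector<int> b;
      b.push_back(edge_rank[(size_t)v[0] * n + v[1]]);
      b.push_back(edge_rank[(size_t)v[0] * n + v[2]]);
      b.push_back(edge_rank[(size_t)v[1] * n + v[2]]);
      std::sort(b.begin(), b.end());
      bnd[t] = b;
    }
    std::vector<int> pivot_of_edge;
    std::vector<char> tri_zero;
    reduce_dim(bnd, tri_cleared, ne, pivot_of_edge, tri_zero);
    std::vector<bool> edge_paired(ne, false);
    for (int e = 0; e < ne; ++e) {
      const int c = pivot_of_edge[e];
      if (c < 0) continue;
      edge_paired[e] = true;
      if (tris[c].filt > edges[e].filt) {
        feat_dim.push_back(1);
        feat_birth.push_back(edges[e].filt);
        feat_death.push_back(tris[c].filt);
      }
    }
    for (int e = 0; e < ne; ++e)
      if (edge_positive[e] && !edge_paired[e]) {
        feat_dim.push_back(1);
        feat_birth.push_back(edges[e].filt);
        feat_death.push_back(R_PosInf);
      }
    if (max_simplex_dim >= 3) {
      // essential H2: positive triangles never paired with a tetrahedron
      for (int t = 0; t < nt; ++t)
        if (tri_zero[t] && !tri_pivot_used[t]) {
          feat_dim.push_back(2);
          feat_birth.push_back(tris[t].filt);
          feat_death.push_back(R_PosInf);
        }
    }
  }

  NumericMatrix out((int)feat_dim.size(), 3);
  for (int i = 0; i < (int)feat_dim.size(); ++i) {
    out(i, 0) = feat_dim[i];
    out(i, 1) = feat_birth[i];
    out(i, 2) = feat_death[i];
  }
  colnames(out) = CharacterVector::create("dimension", "birth", "death");
  return out;
}
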