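#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ToMATo: persistence-based clustering by mode seeking on a density estimate
// over a fixed-radius (Rips) graph, followed by a union-find sweep in
// decreasing density order that merges candidate clusters whose topographic
// prominence (birth density minus saddle density) falls below tau.
//
// Conventions (deterministic with integer-valued densities):
//  * a detection is a mode iff it has no neighbour of strictly higher density;
//  * non-modes attach to the neighbour of maximal density among the strictly
//    higher ones, ties broken towards the lower index;
//  * when two candidates meet at a saddle, the one with the lower birth
//    density dies there (ties: the candidate whose mode has the larger index
//    dies, so lower-index modes persist);
//  * candidates that survive the sweep become clusters when their prominence
//    reaches tau; a root never contacted by a higher-birth candidate uses
//    death level 0 for this test (so weak isolated components are noise),
//    while the ToMATo diagram records its death as -Inf.

struct UF {
  std::vector<int> parent;
  UF(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
};

// [[Rcpp::export(rng = false)]]
List tomato_cpp(List nb, NumericVector f, double tau) {
  const int n = f.size();
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (f[a] != f[b]) return f[a] > f[b];
    return a < b;
  });
  std::vector<int> rank(n);
  for (int i = 0; i < n; ++i) rank[order[i]] = i;

  UF uf(n);
  // candidate bookkeeping, indexed by mode vertex
  std::vector<int> cand_mode;            // mode vertex of each candidate
  std::vector<double> cand_birth, cand_death;
  std::vector<bool> cand_merged;
  std::vector<int> cand_of_root(n, -1);  // candidate index for current roots

  std::vector<int> procnb;
  for (int oi = 0; oi < n; ++oi) {
    const int i = order[oi];
    IntegerVector nbi = nb[i];
    procnb.clear();
    int grad = -1;  // pseudo-gradient target: strictly higher f, maximal f
    for (int k = 0; k < nbi.size(); ++k) {
      const int j = nbi[k] - 1;
      if (rank[j] < rank[i]) procnb.push_back(j);
      if (f[j] > f[i] && (grad < 0 || f[j] > f[grad] || (f[j] == f[grad] && j < grad)))
        grad = j;
    }
    if (grad < 0) {  // new mode -> new candidate
      const int c = (int)cand_mode.size();
      cand_mode.push_back(i);
      cand_birth.push_back(f[i]);
      cand_death.push_back(NA_REAL);
      cand_merged.push_back(false);
      cand_of_root[i] = c;
    } else {
      uf.parent[i] = uf.find(grad);
    }
    // saddle handling against all previously processed neighbours
    for (size_t k = 0; k < procnb.size(); ++k) {
      int ri = uf.find(i);
      int rj = uf.find(procnb[k]);
      if (ri == rj) continue;
      int ci = cand_of_root[ri], cj = cand_of_root[rj];
      // lo = candidate that dies (lower birth; ties -> larger mode index)
      bool i_lo;
      if (cand_birth[ci] != cand_birth[cj]) i_lo = cand_birth[ci] < cand_birth[cj];
      else i_lo = cand_mode[ci] > cand_mode[cj];
      const int clo = i_lo ? ci : cj, chi = i_lo ? cj : ci;
      const int rlo = i_lo ? ri : rj, rhi = i_lo ? rj : ri;
      if (ISNA(cand_death[clo])) cand_death[clo] = f[i];
      if (cand_birth[clo] - f[i] < tau) {  // merge weak candidate upward
        uf.parent[rlo] = rhi;
        cand_merged[clo] = true;
        cand_of_root[uf.find(rhi)] = chi;
      }
    }
  }

  // final roots and cluster designation
  std::vector<int> root(n);
  for (int i = 0; i < n; ++i) root[i] = uf.find(i);
  const int ncand = (int)cand_mode.size();
  std::vector<int> cand_label(ncand, 0);
  // surviving candidates, ordered by (birth desc, mode asc) for label ids
  std::vector<int> surv;
  for (int c = 0; c < ncand; ++c) if (!cand_merged[c]) surv.push_back(c);
  std::sort(surv.begin(), surv.end(), [&](int a, int b) {
    if (cand_birth[a] != cand_birth[b]) return cand_birth[a] > cand_birth[b];
    return cand_mode[a] < cand_mode[b];
  });
  int next = 1;
  for (size_t s = 0; s < surv.size(); ++s) {
    const int c = surv[s];
    const double death0 = ISNA(cand_death[c]) ? 0.0 : cand_death[c];
    if (cand_birth[c] - death0 >= tau) cand_label[c] = next++;
  }
  IntegerVector labels(n);
  for (int i = 0; i < n; ++i) {
    const int c = cand_of_root[root[i]];
    labels[i] = cand_label[c];
  }

  NumericMatrix diag(ncand, 3);
  IntegerVector dmode(ncand), dlabel(ncand);
  for (int c = 0; c < ncand; ++c) {
    dmode[c] = cand_mode[c] + 1;
    diag(c, 0) = cand_birth[c];
    diag(c, 1) = ISNA(cand_death[c]) ? R_NegInf : cand_death[c];
    diag(c, 2) = cand_merged[c] ? 1.0 : 0.0;
    // label of the cluster this candidate ended up in (0 = noise)
    dlabel[c] = labels[cand_mode[c]];
  }
  return List::create(_["labels"] = labels, _["mode"] = dmode,
                      _["diagram"] = diag, _["cand_label"] = dlabel);
}

// DBSCAN on a precomputed fixed-radius neighbour graph. The neighbour count
// for the core test includes the point itself.
// [[Rcpp::export(rng = false)]]
IntegerVector dbscan_cpp(List nb, int min_pts) {
  const int n = nb.size();
  std::vector<bool> core(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nbi = nb[i];
    core[i] = (nbi.size() + 1 >= min_pts);
  }
  IntegerVector labels(n, 0);
  int next = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (!core[i] || labels[i] != 0) continue;
    ++next;
    labels[i] = next;
    stack.assign(1, i);
    while (!stack.empty()) {
      const int v = stack.back(); stack.pop_back();
      IntegerVector nbv = nb[v];
      for (int k = 0; k < nbv.size(); ++k) {
        const int j = nbv[k] - 1;
        if (labels[j] == 0) {
          labels[j] = next;                 // border or core reachable point
          if (core[j]) stack.push_back(j);  // expand only through cores
        }
      }
    }
  }
  return labels;
}
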