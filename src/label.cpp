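#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Union-find connected-component labeling of TRUE cells.
// connectivity: 4 or 8. Returns an integer matrix of component labels
// (0 = background); labels are ordered by each component's first cell in
// row-major (row, then col) order, i.e. by (min row, min col).

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra == rb) return;
  if (ra < rb) parent[rb] = ra; else parent[ra] = rb;
}

// [[Rcpp::export(name = ".label_cc")]]
IntegerMatrix label_cc(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  // provisional ids in row-major scan order
  std::vector<int> cell_of; // provisional id -> linear index (r * nc + c)
  int n = 0;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (mask(r, c)) {
        lab(r, c) = ++n;
        cell_of.push_back(r * nc + c);
      }
  if (n == 0) return lab;
  std::vector<int> parent(n + 1);
  for (int i = 0; i <= n; ++i) parent[i] = i;

  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c)) continue;
      int me = lab(r, c);
      if (c > 0 && mask(r, c - 1)) uf_union(parent, me, lab(r, c - 1));
      if (r > 0 && mask(r - 1, c)) uf_union(parent, me, lab(r - 1, c));
      if (connectivity == 8 && r > 0) {
        if (c > 0 && mask(r - 1, c - 1)) uf_union(parent, me, lab(r - 1, c - 1));
        if (c < nc - 1 && mask(r - 1, c + 1)) uf_union(parent, me, lab(r - 1, c + 1));
      }
    }
  }
  // relabel compactly in order of first appearance of each root (row-major)
  std::vector<int> newlab(n + 1, 0);
  int k = 0;
  for (int i = 1; i <= n; ++i) {
    int root = uf_find(parent, i);
    if (newlab[root] == 0) newlab[root] = ++k;
  }
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (lab(r, c)) lab(r, c) = newlab[uf_find(parent, lab(r, c))];
  return lab;
}
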