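#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Two-pass connected-component labeling with union-find, supporting both
// 4- and 8-connectivity (the installed labeling routines are 4-connected
// only). Labels are positive integers in first-encounter order.

static int find_root(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void unite(std::vector<int> &parent, int a, int b) {
  int ra = find_root(parent, a), rb = find_root(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity = 8) {
  const int nr = mask.nrow(), nc = mask.ncol();
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const bool eight = connectivity == 8;
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int up = (i > 0) ? lab(i - 1, j) : 0;
      int left = (j > 0) ? lab(i, j - 1) : 0;
      int ul = (eight && i > 0 && j > 0) ? lab(i - 1, j - 1) : 0;
      int dl = (eight && i < nr - 1 && j > 0) ? lab(i + 1, j - 1) : 0;
      int neigh[4] = {up, left, ul, dl};
      int lmin = 0;
      for (int k = 0; k < 4; ++k)
        if (neigh[k] > 0 && (lmin == 0 || neigh[k] < lmin)) lmin = neigh[k];
      if (lmin == 0) {
        int fresh = (int)parent.size();
        parent.push_back(fresh);
        lab(i, j) = fresh;
      } else {
        lab(i, j) = lmin;
        for (int k = 0; k < 4; ++k)
          if (neigh[k] > 0) unite(parent, neigh[k], lmin);
      }
    }
  }

  // compress and renumber in first-encounter order
  std::vector<int> newlab(parent.size(), 0);
  int next = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) > 0) {
        int r = find_root(parent, lab(i, j));
        if (newlab[r] == 0) newlab[r] = ++next;
        lab(i, j) = newlab[r];
      }
  return lab;
}
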