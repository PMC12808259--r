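#include <Rcpp.h>
#include <vector>

// Two-pass connected-component labelling with union-find, 4- or
// 8-connectivity. Input: logical matrix (foreground = TRUE). Output: integer
// matrix, 0 = background, components numbered 1..K in raster order of first
// appearance.

static int find_root(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]]; // path halving
    x = parent[x];
  }
  return x;
}

static void unite(std::vector<int> &parent, int a, int b) {
  int ra = find_root(parent, a), rb = find_root(parent, b);
  if (ra == rb) return;
  if (ra < rb) parent[rb] = ra; else parent[ra] = rb;
}

// [[Rcpp::export(name = ".label_cc")]]
Rcpp::IntegerMatrix label_cc(Rcpp::LogicalMatrix mask, int connectivity) {
  const int h = mask.nrow(), w = mask.ncol();
  Rcpp::IntegerMatrix lab(h, w);
  std::vector<int> parent(1, 0); // parent[0] unused
  int next = 1;

  const bool diag = (connectivity == 8);

  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (!mask(i, j)) continue;
      int up    = (i > 0 && mask(i - 1, j)) ? lab(i - 1, j) : 0;
      int left  = (j > 0 && mask(i, j - 1)) ? lab(i, j - 1) : 0;
      int ul = 0, dl = 0;
      if (diag) {
        ul = (i > 0 && j > 0 && mask(i - 1, j - 1)) ? lab(i - 1, j - 1) : 0;
        dl = (i + 1 < h && j > 0 && mask(i + 1, j - 1)) ? lab(i + 1, j - 1) : 0;
      }
      int neigh[4] = {up, left, ul, dl};
      int lmin = 0;
      for (int k = 0; k < 4; ++k)
        if (neigh[k] > 0 && (lmin == 0 || neigh[k] < lmin)) lmin = neigh[k];
      if (lmin == 0) {
        parent.push_back(next);
        lab(i, j) = next++;
      } else {
        lab(i, j) = lmin;
        for (int k = 0; k < 4; ++k)
          if (neigh[k] > 0) unite(parent, lmin, neigh[k]);
      }
    }
  }

  // flatten and renumber roots consecutively in raster order
  std::vector<int> newlab(next, 0);
  int count = 0;
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      int r = find_root(parent, l);
      if (newlab[r] == 0) newlab[r] = ++count;
      lab(i, j) = newlab[r];
    }
  }
  return lab;
}
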