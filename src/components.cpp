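#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Union-find with path compression.
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// 8-connected component labeling of a binary mask.
// Labels are numbered 1..K in raster order (row-major scan) of each
// component's first pixel.
// [[Rcpp::export(name = ".label_components_8")]]
IntegerMatrix label_components_8(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next_label = 0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next_label;
      stack.clear();
      stack.push_back(r * nc + c);
      lab(r, c) = next_label;
      while (!stack.empty()) {
        int id = stack.back();
        stack.pop_back();
        int cr = id / nc, cc = id % nc;
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int rr = cr + dr, cc2 = cc + dc;
            if (rr < 0 || rr >= nr || cc2 < 0 || cc2 >= nc) continue;
            if (mask(rr, cc2) && lab(rr, cc2) == 0) {
              lab(rr, cc2) = next_label;
              stack.push_back(rr * nc + cc2);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Local maxima by topographic prominence (descending flood, 8-connected).
// A maximum is reported when the saddle connecting it to any higher maximum
// lies more than `prominence` below its peak. Plateaus resolve to the first
// plateau pixel in raster order. Returns a matrix with columns
// (row, col, value), 1-based indices, rows ordered by raster position.
// [[Rcpp::export(name = ".find_maxima_prominence")]]
NumericMatrix find_maxima_prominence(const NumericMatrix& img, double prominence) {
  const int nr = img.nrow(), nc = img.ncol();
  const int n = nr * nc;
  // raster-major ids: id = r * nc + c
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::vector<double> val(n);
  double vmin = R_PosInf;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      val[r * nc + c] = img(r, c);
      if (img(r, c) < vmin) vmin = img(r, c);
    }
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (val[a] != val[b]) return val[a] > val[b];
    return a < b;  // raster-order tie-break
  });

  std::vector<int> parent(n), peak(n);
  std::vector<char> seen(n, 0);
  std::vector<int> accepted;

  for (int k = 0; k < n; ++k) {
    const int p = order[k];
    const int pr = p / nc, pc = p % nc;
    const double h = val[p];
    int roots[8];
    int nroots = 0;
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dc = -1; dc <= 1; ++dc) {
        if (dr == 0 && dc == 0) continue;
        int rr = pr + dr, cc = pc + dc;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int q = rr * nc + cc;
        if (!seen[q]) continue;
        int root = uf_find(parent, q);
        bool dup = false;
        for (int i = 0; i < nroots; ++i)
          if (roots[i] == root) { dup = true; break; }
        if (!dup) roots[nroots++] = root;
      }
    }
    seen[p] = 1;
    if (nroots == 0) {
      parent[p] = p;
      peak[p] = p;
      continue;
    }
    // winner: root whose peak is highest (tie: earliest raster peak)
    int win = roots[0];
    for (int i = 1; i < nroots; ++i) {
      int r2 = roots[i];
      double pw = val[peak[win]], p2 = val[peak[r2]];
      if (p2 > pw || (p2 == pw && peak[r2] < peak[win])) win = r2;
    }
    for (int i = 0; i < nroots; ++i) {
      int r2 = roots[i];
      if (r2 == win) continue;
      // component r2 merges into a higher component at saddle level h
      if (val[peak[r2]] - h >= prominence) accepted.push_back(peak[r2]);
      parent[r2] = win;
    }
    parent[p] = win;
  }

  // the last surviving component (contains the global maximum)
  if (n > 0) {
    int root = uf_find(parent, order[0]);
    if (val[peak[root]] - vmin >= prominence) accepted.push_back(peak[root]);
  }

  std::sort(accepted.begin(), accepted.end());
  NumericMatrix out(accepted.size(), 3);
  for (size_t i = 0; i < accepted.size(); ++i) {
    int id = accepted[i];
    out(i, 0) = id / nc + 1;
    out(i, 1) = id % nc + 1;
    out(i, 2) = val[id];
  }
  colnames(out) = CharacterVector::create("row", "col", "value");
  return out;
}
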