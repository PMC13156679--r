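#include <Rcpp.h>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// Connected-component labeling of a logical matrix by breadth-first search.
// connectivity must be 4 or 8. Returns an integer matrix, 0 = background,
// components numbered 1..n in raster-scan order of their first pixel.
// [[Rcpp::export(name = ".labelComponents")]]
IntegerMatrix label_components(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr4[] = {-1, 1, 0, 0},            dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dr = connectivity == 8 ? dr8 : dr4;
  const int* dc = connectivity == 8 ? dc8 : dc4;
  const int nd = connectivity == 8 ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int d = 0; d < nd; ++d) {
          int rr = p.first + dr[d], cc = p.second + dc[d];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

// In-place co-clustering accumulator: C[idx, idx] += w for 1-based idx.
// [[Rcpp::export(name = ".ccAddBlock")]]
void cc_add_block(NumericMatrix C, const IntegerVector& idx, double w) {
  const int n = C.nrow(), m = idx.size();
  for (int b = 0; b < m; ++b) {
    const int j = idx[b] - 1;
    double* col = &C(0, j);
    for (int a = 0; a < m; ++a) col[idx[a] - 1] += w;
    (void)n;
  }
}

// For each column of a symmetric distance matrix return the 1-based indices of
// the kmax smallest entries in increasing order, ties broken by index.
// [[Rcpp::export(name = ".knnOrder")]]
IntegerMatrix knn_order(const NumericMatrix& D, int kmax) {
  const int n = D.ncol();
  if (kmax > n) stop("kmax exceeds the number of points");
  IntegerMatrix out(kmax, n);
  std::vector<int> ord(n);
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < n; ++i) ord[i] = i;
    const double* col = &D(0, j);
    std::partial_sort(ord.begin(), ord.begin() + kmax, ord.end(),
                      [col](int a, int b) {
                        if (col[a] != col[b]) return col[a] < col[b];
                        return a < b;
                      });
    for (int k = 0; k < kmax; ++k) out(k, j) = ord[k] + 1;
  }
  return out;
}
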