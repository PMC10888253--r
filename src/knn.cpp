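#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Exact k-nearest-neighbour search by blocked brute force.
//
// Flow-cytometry event tables are wide enough (10+ standardized channels)
// that spatial trees degenerate to brute force with extra overhead, so we
// scan all pairs directly.  The event matrix is kept as per-channel float
// arrays so the squared-distance accumulation vectorizes over events, and a
// bounded max-heap of size k avoids materializing full distance rows.
// Distances are accumulated in single precision (inputs are standardized,
// values O(10)); the returned distances are exact to float rounding.
// [[Rcpp::export(name = ".cg_knn")]]
List cg_knn(const NumericMatrix& X, const int k) {
  const int n = X.nrow(), d = X.ncol();
  if (k < 1 || k >= n) stop("k must be in [1, nrow(X) - 1]");
  std::vector< std::vector<float> > xc(d, std::vector<float>(n));
  for (int t = 0; t < d; ++t)
    for (int j = 0; j < n; ++j) xc[t][j] = (float)X(j, t);
  IntegerMatrix idx(n, k);
  NumericMatrix dist(n, k);
  const int B = 4096;
  std::vector<float> buf(B);
  std::vector< std::pair<float,int> > heap;
  heap.reserve(k + 1);
  for (int i = 0; i < n; ++i) {
    heap.clear();
    float worst = std::numeric_limits<float>::infinity();
    for (int b0 = 0; b0 < n; b0 += B) {
      const int bl = std::min(n - b0, B);
      {
        const float xi0 = xc[0][i];
        const float* col = &xc[0][b0];
        for (int j = 0; j < bl; ++j) { float df = xi0 - col[j]; buf[j] = df * df; }
      }
      for (int t = 1; t < d; ++t) {
        const float xit = xc[t][i];
        const float* col = &xc[t][b0];
        for (int j = 0; j < bl; ++j) { float df = xit - col[j]; buf[j] += df * df; }
      }
      for (int j = 0; j < bl; ++j) {
        const int jj = b0 + j;
        if (jj == i) continue;
        const float s = buf[j];
        if ((int)heap.size() < k) {
          heap.push_back(std::make_pair(s, jj));
          std::push_heap(heap.begin(), heap.end());
          if ((int)heap.size() == k) worst = heap.front().first;
        } else if (s < worst) {
          std::pop_heap(heap.begin(), heap.end());
          heap.back() = std::make_pair(s, jj);
          std::push_heap(heap.begin(), heap.end());
          worst = heap.front().first;
        }
      }
    }
    std::sort_heap(heap.begin(), heap.end());
    for (int j = 0; j < (int)heap.size(); ++j) {
      idx(i, j) = heap[j].second + 1;
      dist(i, j) = std::sqrt(std::max(0.0, (double)heap[j].first));
    }
  }
  return List::create(_["nn.index"] = idx, _["nn.dist"] = dist);
}
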