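#include <RcppArmadillo.h>
#include <queue>
#include <utility>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Minority vote fraction among the k nearest training rows of each test row.
// Distances are Euclidean; candidates are ranked by the expansion
// ||t||^2 - 2 t.x (the test row's own norm is constant within a row and
// dropped). Ties in distance are broken by smaller training-row index,
// matching the package's deterministic neighbor rule: training rows are
// scanned in ascending index order and an equal-distance later row never
// displaces an earlier one from the heap.
// [[Rcpp::export(name = ".knnVoteCpp")]]
NumericVector knnVoteCpp(const arma::mat &train, const IntegerVector &y,
                         const arma::mat &test, int k) {
  const int n = train.n_rows, m = test.n_rows;
  if (k < 1 || k > n) stop("k out of range");
  if ((int) y.size() != n) stop("label length mismatch");
  if (test.n_cols != train.n_cols) stop("feature dimension mismatch");
  arma::vec trainNorm = arma::sum(arma::square(train), 1);
  arma::mat cross = train * test.t();  // n x m
  NumericVector prob(m);
  typedef std::pair<double, int> cand;
  for (int i = 0; i < m; ++i) {
    std::priority_queue<cand> heap;  // top = worst of the current k best
    const double *cr = cross.colptr(i);
    for (int j = 0; j < n; ++j) {
      cand c(trainNorm[j] - 2.0 * cr[j], j);
      if ((int) heap.size() < k) {
        heap.push(c);
      } else if (c < heap.top()) {
        heap.pop();
        heap.push(c);
      }
    }
    int votes = 0;
    while (!heap.empty()) {
      if (y[heap.top().second] == 1) ++votes;
      heap.pop();
    }
    prob[i] = static_cast<double>(votes) / k;
  }
  return prob;
}
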