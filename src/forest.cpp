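// Random forest for small two-class problems: CART with Gini splitting,
// bootstrap resampling and per-split feature subsampling.  Trees are not
// stored; each tree classifies the test matrix while it is grown, and the
// per-feature Gini impurity decreases are accumulated on the fly.
// Uses R's RNG so results follow set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Problem {
  const NumericMatrix &X, &Xt;
  const IntegerVector &y;     // 0/1 labels, length n
  int mtry, min_node;
  std::vector<double> importance;          // per feature, accumulated
  std::vector<double> votes;               // per test row, accumulated
  int n_total;                             // bootstrap sample size
};

double gini(int n0, int n1) {
  double n = n0 + n1;
  if (n == 0) return 0.0;
  double p0 = n0 / n, p1 = n1 / n;
  return 1.0 - p0 * p0 - p1 * p1;
}

// Grow one node on the (bootstrap) training rows `idx`, routing the test
// rows `tidx` down the same splits; leaves vote with their majority class.
void grow(Problem &P, std::vector<int> &idx, std::vector<int> &tidx,
          int depth) {
  int n = idx.size();
  int n1 = 0;
  for (int i : idx) n1 += P.y[i];
  int n0 = n - n1;

  double node_imp = gini(n0, n1);
  bool leaf = (n < P.min_node) || node_imp == 0.0 || depth > 64;

  int best_f = -1;
  double best_thr = 0.0, best_dec = 1e-12;
  if (!leaf) {
    int p = P.X.ncol();
    // sample mtry distinct features (partial Fisher-Yates on 0..p-1)
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(P.mtry, p);
    for (int j = 0; j < m; ++j) {
      int k = j + (int)(unif_rand() * (p - j));
      if (k >= p) k = p - 1;
      std::swap(feats[j], feats[k]);
    }
    std::vector<std::pair<double, int>> v(n);
    for (int j = 0; j < m; ++j) {
      int f = feats[j];
      for (int i = 0; i < n; ++i)
        v[i] = {P.X(idx[i], f), P.y[idx[i]]};
      std::sort(v.begin(), v.end());
      int l0 = 0, l1 = 0;
      for (int i = 0; i + 1 < n; ++i) {
        if (v[i].second) ++l1; else ++l0;
        if (v[i].first == v[i + 1].first) continue;  // not a cut point
        double dec = node_imp -
          (double)(i + 1) / n * gini(l0, l1) -
          (double)(n - i - 1) / n * gini(n0 - l0, n1 - l1);
        if (dec > best_dec) {
          best_dec = dec;
          best_f = f;
          best_thr = 0.5 * (v[i].first + v[i + 1].first);
        }
      }
    }
    if (best_f < 0) leaf = true;
  }

  if (leaf) {
    double vote = (n1 > n0) ? 1.0 : (n1 < n0 ? 0.0 : 0.5);
    for (int i : tidx) P.votes[i] += vote;
    return;
  }

  // weighted decrease relative to the full bootstrap sample
  P.importance[best_f] += best_dec * n / P.n_total;

  std::vector<int> li, ri, lt, rt;
  for (int i : idx)
    (P.X(i, best_f) <= best_thr ? li : ri).push_back(i);
  for (int i : tidx)
    (P.Xt(i, best_f) <= best_thr ? lt : rt).push_back(i);
  grow(P, li, lt, depth + 1);
  grow(P, ri, rt, depth + 1);
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_predict")]]
List rf_fit_predict(NumericMatrix X, IntegerVector y, NumericMatrix Xtest,
                    int ntree, int mtry, int min_node) {
  int n = X.nrow(), nt = Xtest.nrow();
  if (y.size() != n) stop("length(y) must match nrow(X)");
  RNGScope scope;
  Problem P{X, Xtest, y, mtry, std::max(2, min_node),
            std::vector<double>(X.ncol(), 0.0),
            std::vector<double>(nt, 0.0), n};
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n), tidx(nt);
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * n);
      idx[i] = (k >= n) ? n - 1 : k;
    }
    for (int i = 0; i < nt; ++i) tidx[i] = i;
    grow(P, idx, tidx, 0);
  }
  NumericVector imp(P.importance.begin(), P.importance.end());
  NumericVector vote(nt);
  IntegerVector pred(nt);
  for (int i = 0; i < nt; ++i) {
    vote[i] = P.votes[i] / ntree;
    pred[i] = vote[i] > 0.5 ? 1 : 0;
  }
  imp = imp / ntree;
  return List::create(_["prediction"] = pred, _["vote"] = vote,
                      _["importance"] = imp);
}
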