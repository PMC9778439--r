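#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Gradient-boosted regression trees with a multi-class softmax objective.
// Exact greedy split search (no histogram binning) -- adequate for the
// patch-classification problem sizes (n <= a few thousand, p ~ 200).
// Regularized gain as in the usual second-order formulation:
//   gain = 0.5 * (GL^2/(HL+lambda) + GR^2/(HR+lambda) - G^2/(H+lambda)) - gamma
// Leaf weight = -G/(H+lambda), scaled by the learning rate at build time.

struct FlatTree {
  std::vector<int> feature, left, right;      // feature < 0 => leaf
  std::vector<double> thresh, value;
};

struct SplitInfo {
  int feature;
  double thresh, gain;
  bool ok;
};

static SplitInfo best_split(const NumericMatrix& X, const std::vector<int>& idx,
                            const std::vector<double>& g, const std::vector<double>& h,
                            double lambda, double gamma, double min_child_weight) {
  SplitInfo best; best.ok = false; best.gain = 0.0; best.feature = -1; best.thresh = 0.0;
  int n = idx.size(), p = X.ncol();
  double G = 0.0, H = 0.0;
  for (int i = 0; i < n; ++i) { G += g[idx[i]]; H += h[idx[i]]; }
  double parent = G * G / (H + lambda);

  std::vector<std::pair<double, int> > vals(n);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) vals[i] = std::make_pair(X(idx[i], j), idx[i]);
    std::sort(vals.begin(), vals.end());
    double GL = 0.0, HL = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      GL += g[vals[i].second];
      HL += h[vals[i].second];
      if (vals[i].first == vals[i + 1].first) continue;
      double GR = G - GL, HR = H - HL;
      if (HL < min_child_weight || HR < min_child_weight) continue;
      double gain = 0.5 * (GL * GL / (HL + lambda) + GR * GR / (HR + lambda) - parent) - gamma;
      if (gain > best.gain + 1e-12) {
        best.ok = true;
        best.gain = gain;
        best.feature = j;
        best.thresh = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  return best;
}

static int build_node(FlatTree& t, const NumericMatrix& X, const std::vector<int>& idx,
                      const std::vector<double>& g, const std::vector<double>& h,
                      int depth, int max_depth, double lambda, double gamma,
                      double min_child_weight, double eta) {
  int node = t.feature.size();
  t.feature.push_back(-1); t.thresh.push_back(0.0);
  t.left.push_back(-1); t.right.push_back(-1); t.value.push_back(0.0);

  double G = 0.0, H = 0.0;
  for (size_t i = 0; i < idx.size(); ++i) { G += g[idx[i]]; H += h[idx[i]]; }

  SplitInfo s;
  s.ok = false;
  if (depth < max_depth && idx.size() >= 2)
    s = best_split(X, idx, g, h, lambda, gamma, min_child_weight);

  if (!s.ok) {
    t.value[node] = -eta * G / (H + lambda);
    return node;
  }
  std::vector<int> li, ri;
  for (size_t i = 0; i < idx.size(); ++i) {
    if (X(idx[i], s.feature) < s.thresh) li.push_back(idx[i]);
    else ri.push_back(idx[i]);
  }
  t.feature[node] = s.feature;
  t.thresh[node] = s.thresh;
  int l = build_node(t, X, li, g, h, depth + 1, max_depth, lambda, gamma, min_child_weight, eta);
  int r = build_node(t, X, ri, g, h, depth + 1, max_depth, lambda, gamma, min_child_weight, eta);
  t.left[node] = l;
  t.right[node] = r;
  return node;
}

static double tree_predict_one(const List& tree, const NumericMatrix& X, int row) {
  IntegerVector feature = tree["feature"];
  NumericVector thresh = tree["thresh"];
  IntegerVector left = tree["left"], right = tree["right"];
  NumericVector value = tree["value"];
  int node = 0;
  while (feature[node] >= 0)
    node = (X(row, feature[node]) < thresh[node]) ? left[node] : right[node];
  return value[node];
}

static List flat_to_list(const FlatTree& t) {
  return List::create(_["feature"] = wrap(t.feature), _["thresh"] = wrap(t.thresh),
                      _["left"] = wrap(t.left), _["right"] = wrap(t.right),
                      _["value"] = wrap(t.value));
}

// [[Rcpp::export]]
List gbt_train_cpp(const NumericMatrix& X, const IntegerVector& y, int K,
                   int nrounds, double eta, int max_depth, double lambda,
                   double gamma, double min_child_weight) {
  int n = X.nrow();
  std::vector<std::vector<double> > F(n, std::vector<double>(K, 0.0));
  std::vector<double> g(n), h(n);
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;

  List trees(nrounds * K);
  std::vector<double> prob(K);
  for (int round = 0; round < nrounds; ++round) {
    for (int k = 0; k < K; ++k) {
      for (int i = 0; i < n; ++i) {
        double mx = F[i][0];
        for (int kk = 1; kk < K; ++kk) mx = std::max(mx, F[i][kk]);
        double denom = 0.0;
        for (int kk = 0; kk < K; ++kk) denom += std::exp(F[i][kk] - mx);
        double pk = std::exp(F[i][k] - mx) / denom;
        g[i] = pk - (y[i] == k ? 1.0 : 0.0);
        h[i] = std::max(pk * (1.0 - pk), 1e-16);
      }
      FlatTree t;
      build_node(t, X, all, g, h, 0, max_depth, lambda, gamma, min_child_weight, eta);
      for (int i = 0; i < n; ++i) {
        int node = 0;
        while (t.feature[node] >= 0)
          node = (X(i, t.feature[node]) < t.thresh[node]) ? t.left[node] : t.right[node];
        F[i][k] += t.value[node];
      }
      trees[round * K + k] = flat_to_list(t);
    }
  }
  return trees;
}

// Returns the n x K matrix of boosted margins (pre-softmax scores).
// [[Rcpp::export]]
NumericMatrix gbt_margin_cpp(const List& trees, const NumericMatrix& X, int K) {
  int n = X.nrow(), m = trees.size();
  NumericMatrix out(n, K);
  for (int t = 0; t < m; ++t) {
    List tree = trees[t];
    int k = t % K;
    for (int i = 0; i < n; ++i) out(i, k) += tree_predict_one(tree, X, i);
  }
  return out;
}
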