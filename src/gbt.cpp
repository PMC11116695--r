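// Second-order (Newton) gradient-boosted trees with logistic loss and L2
// leaf regularization: per leaf j with gradient sum G_j and hessian sum H_j
// the weight is -G_j/(H_j + lambda) and the split gain is
//   1/2 [ G_L^2/(H_L+lambda) + G_R^2/(H_R+lambda) - G^2/(H+lambda) ] - gamma.
// Exact greedy split search over all features; fully deterministic (no
// subsampling), ties resolved by lowest feature index / threshold.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;          // -1 => leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  double value = 0.0;        // leaf weight
};

struct TreeBuilder {
  const NumericMatrix& X;
  const std::vector<double>& g;
  const std::vector<double>& h;
  double lambda, gamma, min_child_weight;
  int max_depth;
  std::vector<Node> nodes;

  TreeBuilder(const NumericMatrix& X_, const std::vector<double>& g_,
              const std::vector<double>& h_, double lambda_, double gamma_,
              double mcw_, int max_depth_)
    : X(X_), g(g_), h(h_), lambda(lambda_), gamma(gamma_),
      min_child_weight(mcw_), max_depth(max_depth_) {}

  int build(std::vector<int>& idx, int depth) {
    double G = 0.0, H = 0.0;
    for (int i : idx) { G += g[i]; H += h[i]; }
    int me = nodes.size();
    nodes.push_back(Node());
    if (depth >= max_depth || idx.size() < 2) {
      nodes[me].value = -G / (H + lambda);
      return me;
    }
    double best_gain = 0.0, best_thr = 0.0;
    int best_feat = -1;
    double parent_score = G * G / (H + lambda);
    int p = X.ncol();
    std::vector<std::pair<double, int>> vals;
    vals.reserve(idx.size());
    for (int f = 0; f < p; ++f) {
      vals.clear();
      for (int i : idx) vals.push_back({X(i, f), i});
      std::sort(vals.begin(), vals.end());
      double GL = 0.0, HL = 0.0;
      for (size_t r = 0; r + 1 < vals.size(); ++r) {
        GL += g[vals[r].second];
        HL += h[vals[r].second];
        if (vals[r].first == vals[r + 1].first) continue;
        double GR = G - GL, HR = H - HL;
        if (HL < min_child_weight || HR < min_child_weight) continue;
        double gain = 0.5 * (GL * GL / (HL + lambda) + GR * GR / (HR + lambda)
                             - parent_score) - gamma;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_feat = f;
          best_thr = 0.5 * (vals[r].first + vals[r + 1].first);
        }
      }
    }
    if (best_feat < 0) {
      nodes[me].value = -G / (H + lambda);
      return me;
    }
    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_feat) < best_thr) li.push_back(i); else ri.push_back(i);
    }
    nodes[me].feature = best_feat;
    nodes[me].threshold = best_thr;
    nodes[me].left = build(li, depth + 1);
    nodes[me].right = build(ri, depth + 1);
    return me;
  }
};

double tree_predict(const std::vector<Node>& nodes, const NumericMatrix& X,
                    int row) {
  int cur = 0;
  while (nodes[cur].feature >= 0) {
    cur = (X(row, nodes[cur].feature) < nodes[cur].threshold)
            ? nodes[cur].left : nodes[cur].right;
  }
  return nodes[cur].value;
}

List pack_tree(const std::vector<Node>& nodes) {
  int n = nodes.size();
  IntegerVector feature(n), left(n), right(n);
  NumericVector threshold(n), value(n);
  for (int i = 0; i < n; ++i) {
    feature[i] = nodes[i].feature;
    threshold[i] = nodes[i].threshold;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    value[i] = nodes[i].value;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["value"] = value);
}

std::vector<Node> unpack_tree(const List& tree) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  std::vector<Node> nodes(feature.size());
  for (int i = 0; i < feature.size(); ++i) {
    nodes[i].feature = feature[i];
    nodes[i].threshold = threshold[i];
    nodes[i].left = left[i];
    nodes[i].right = right[i];
    nodes[i].value = value[i];
  }
  return nodes;
}

} // namespace

// [[Rcpp::export]]
List cpp_gbt_train(NumericMatrix X, IntegerVector y, int n_trees,
                   int max_depth, double learning_rate, double lambda,
                   double gamma, double min_child_weight,
                   double base_margin) {
  int n = X.nrow();
  std::vector<double> margin(n, base_margin), g(n), h(n);
  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) {
      double p = 1.0 / (1.0 + std::exp(-margin[i]));
      g[i] = p - y[i];
      h[i] = std::max(p * (1.0 - p), 1e-16);
    }
    TreeBuilder tb(X, g, h, lambda, gamma, min_child_weight, max_depth);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    tb.build(idx, 0);
    for (int i = 0; i < n; ++i)
      margin[i] += learning_rate * tree_predict(tb.nodes, X, i);
    trees[t] = pack_tree(tb.nodes);
  }
  return List::create(_["trees"] = trees,
                      _["train_margin"] = NumericVector(margin.begin(),
                                                        margin.end()));
}

// [[Rcpp::export]]
NumericVector cpp_gbt_predict(List trees, NumericMatrix X,
                              double learning_rate, double base_margin) {
  int n = X.nrow();
  NumericVector margin(n, base_margin);
  for (int t = 0; t < trees.size(); ++t) {
    std::vector<Node> nodes = unpack_tree(trees[t]);
    for (int i = 0; i < n; ++i)
      margin[i] += learning_rate * tree_predict(nodes, X, i);
  }
  return margin;
}
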