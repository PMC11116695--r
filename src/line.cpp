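// LINE node-embedding trainer: stochastic gradient ascent on the
// negative-sampled first/second-order proximity objective, with alias-table
// edge and noise-vertex sampling. Deterministic for a fixed seed (own
// mt19937; no R RNG involvement inside the loop).
#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// Walker alias tables: O(1) draws from a discrete distribution.
struct AliasTable {
  std::vector<double> prob;
  std::vector<int> alias;

  void build(const std::vector<double>& w) {
    int n = w.size();
    prob.assign(n, 0.0);
    alias.assign(n, 0);
    double total = 0.0;
    for (double x : w) total += x;
    std::vector<double> scaled(n);
    for (int i = 0; i < n; ++i) scaled[i] = w[i] * n / total;
    std::vector<int> small, large;
    for (int i = n - 1; i >= 0; --i) {
      if (scaled[i] < 1.0) small.push_back(i); else large.push_back(i);
    }
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int l = large.back(); large.pop_back();
      prob[s] = scaled[s];
      alias[s] = l;
      scaled[l] = scaled[l] + scaled[s] - 1.0;
      if (scaled[l] < 1.0) small.push_back(l); else large.push_back(l);
    }
    while (!large.empty()) { prob[large.back()] = 1.0; large.pop_back(); }
    while (!small.empty()) { prob[small.back()] = 1.0; small.pop_back(); }
  }

  template <class RNG>
  int draw(RNG& rng, double u1, double u2) const {
    int idx = std::min<int>(prob.size() - 1, (int)(u1 * prob.size()));
    return (u2 < prob[idx]) ? idx : alias[idx];
  }
};

inline double unif01(std::mt19937& g) {
  return g() * (1.0 / 4294967296.0);
}

inline double sigmoid(double x) {
  if (x > 35.0) return 1.0;
  if (x < -35.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

} // namespace

// Build an alias table (exposed for unit testing the sampler).
// [[Rcpp::export]]
List cpp_alias_build(NumericVector weights) {
  AliasTable t;
  t.build(std::vector<double>(weights.begin(), weights.end()));
  return List::create(
    _["prob"] = NumericVector(t.prob.begin(), t.prob.end()),
    _["alias"] = IntegerVector(t.alias.begin(), t.alias.end())
  );
}

// Draw n indices (1-based) from the discrete distribution proportional to
// weights, via the alias method.
// [[Rcpp::export]]
IntegerVector cpp_alias_sample(NumericVector weights, int n, int seed) {
  AliasTable t;
  t.build(std::vector<double>(weights.begin(), weights.end()));
  std::mt19937 rng(seed);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double u1 = unif01(rng), u2 = unif01(rng);
    out[i] = t.draw(rng, u1, u2) + 1;
  }
  return out;
}

// Train LINE embeddings of one order.
//   edges:        m x 2 integer matrix, 0-based vertex indices
//   weights:      per-edge positive weights (edge sampling ~ weight)
//   noise:        per-vertex noise weights (degree^{3/4} convention)
//   order:        1 (first-order, vertex.vertex) or 2 (second-order,
//                 vertex.context)
// Each step samples one edge and processes it in both directions; for each
// direction the positive target and K noise vertices are updated
// sequentially while the source accumulates its error vector. The learning
// rate decays linearly from lr0 to lr0/100 over n_samples steps.
// [[Rcpp::export]]
List cpp_train_line(IntegerMatrix edges, NumericVector weights,
                    NumericVector noise, int n_vertices, int dim,
                    int order, int K, double n_samples, double lr0,
                    int seed) {
  int m = edges.nrow();
  std::mt19937 rng(seed);
  AliasTable edge_alias, noise_alias;
  edge_alias.build(std::vector<double>(weights.begin(), weights.end()));
  noise_alias.build(std::vector<double>(noise.begin(), noise.end()));

  // vertex vectors: uniform in [-0.5/dim, 0.5/dim]; context vectors: zero
  std::vector<double> vert((size_t)n_vertices * dim);
  for (auto& x : vert) x = (unif01(rng) - 0.5) / dim;
  std::vector<double> ctx;
  if (order == 2) ctx.assign((size_t)n_vertices * dim, 0.0);
  std::vector<double>& target_store = (order == 2) ? ctx : vert;

  std::vector<double> err(dim);
  long long total = (long long)n_samples;
  for (long long step = 0; step < total; ++step) {
    double lr = lr0 * (1.0 - 0.99 * (double)step / (double)total);
    double u1 = unif01(rng), u2 = unif01(rng);
    int e = edge_alias.draw(rng, u1, u2);
    int ends[2] = { edges(e, 0), edges(e, 1) };
    for (int d = 0; d < 2; ++d) {
      int src = ends[d], tgt = ends[1 - d];
      double* sv = &vert[(size_t)src * dim];
      std::fill(err.begin(), err.end(), 0.0);
      for (int neg = 0; neg <= K; ++neg) {
        int node;
        double label;
        if (neg == 0) {
          node = tgt; label = 1.0;
        } else {
          // a negative must differ from the positive target; with shared
          // vectors (first order) it must also differ from the source, or
          // the self-term sigma(u.u) shrinks every vector toward zero. On
          // tiny graphs no admissible vertex may exist: skip the draw.
          int attempts = 0;
          bool excl_src = (order != 2);
          do {
            double v1 = unif01(rng), v2 = unif01(rng);
            node = noise_alias.draw(rng, v1, v2);
          } while ((node == tgt || (excl_src && node == src)) &&
                   ++attempts < 100);
          if (node == tgt || (excl_src && node == src)) continue;
          label = 0.0;
        }
        double* tv = &target_store[(size_t)node * dim];
        double x = 0.0;
        for (int i = 0; i < dim; ++i) x += sv[i] * tv[i];
        if (!std::isfinite(x)) {
          stop("LINE training diverged (non-finite score) at step %ld", (long)step);
        }
        double g = (label - sigmoid(x)) * lr;
        for (int i = 0; i < dim; ++i) {
          err[i] += g * tv[i];
          tv[i] += g * sv[i];
        }
      }
      for (int i = 0; i < dim; ++i) sv[i] += err[i];
    }
  }

  NumericMatrix vout(n_vertices, dim);
  for (int v = 0; v < n_vertices; ++v)
    for (int i = 0; i < dim; ++i) vout(v, i) = vert[(size_t)v * dim + i];
  if (order == 2) {
    NumericMatrix cout_(n_vertices, dim);
    for (int v = 0; v < n_vertices; ++v)
      for (int i = 0; i < dim; ++i) cout_(v, i) = ctx[(size_t)v * dim + i];
    return List::create(_["vertex"] = vout, _["context"] = cout_);
  }
  return List::create(_["vertex"] = vout, _["context"] = R_NilValue);
}
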