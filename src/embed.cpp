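#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// All randomness below comes from R's RNG (RNGScope via Rcpp attributes),
// so results are reproducible under set.seed()/withr::with_seed().

static inline bool adjacent(const std::vector<std::vector<int>> &adj, int a, int b) {
  const std::vector<int> &v = adj[a];
  return std::binary_search(v.begin(), v.end(), b);
}

static std::vector<std::vector<int>> as_adj(const List &adj_list) {
  int n = adj_list.size();
  std::vector<std::vector<int>> adj(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adj_list[i];
    adj[i] = std::vector<int>(nb.begin(), nb.end());
  }
  return adj;
}

// Unnormalized then normalized one-step probabilities of a second-order
// (node2vec) walk at node v with predecessor t (t = -1: first step, uniform).
// [[Rcpp::export]]
NumericVector cpp_node2vec_step_probs(List adj_list, int t, int v,
                                      double p, double q) {
  std::vector<std::vector<int>> adj = as_adj(adj_list);
  const std::vector<int> &nb = adj[v];
  NumericVector w(nb.size());
  double tot = 0.0;
  for (size_t k = 0; k < nb.size(); ++k) {
    double wk;
    if (t < 0) {
      wk = 1.0;
    } else if (nb[k] == t) {
      wk = 1.0 / p;
    } else if (adjacent(adj, t, nb[k])) {
      wk = 1.0;
    } else {
      wk = 1.0 / q;
    }
    w[k] = wk;
    tot += wk;
  }
  for (size_t k = 0; k < nb.size(); ++k) w[k] /= tot;
  return w;
}

static int sample_weighted(const std::vector<double> &w, double tot) {
  double u = unif_rand() * tot;
  double acc = 0.0;
  for (size_t k = 0; k < w.size(); ++k) {
    acc += w[k];
    if (u <= acc) return (int)k;
  }
  return (int)w.size() - 1;
}

// walks_per_node passes; each pass shuffles the node order and starts one
// walk per node. Walks from isolated nodes have length 1.
// [[Rcpp::export]]
List cpp_node2vec_walks(List adj_list, double p, double q,
                        int walk_length, int walks_per_node) {
  std::vector<std::vector<int>> adj = as_adj(adj_list);
  int n = adj.size();
  List out(n * walks_per_node);
  int pos = 0;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::vector<double> w;
  for (int pass = 0; pass < walks_per_node; ++pass) {
    // Fisher-Yates with R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    for (int s = 0; s < n; ++s) {
      int start = order[s];
      std::vector<int> walk;
      walk.reserve(walk_length);
      walk.push_back(start);
      int prev = -1, cur = start;
      while ((int)walk.size() < walk_length) {
        const std::vector<int> &nb = adj[cur];
        if (nb.empty()) break;
        w.resize(nb.size());
        double tot = 0.0;
        for (size_t k = 0; k < nb.size(); ++k) {
          double wk;
          if (prev < 0) wk = 1.0;
          else if (nb[k] == prev) wk = 1.0 / p;
          else if (adjacent(adj, prev, nb[k])) wk = 1.0;
          else wk = 1.0 / q;
          w[k] = wk;
          tot += wk;
        }
        int k = sample_weighted(w, tot);
        prev = cur;
        cur = nb[k];
        walk.push_back(cur);
      }
      out[pos++] = IntegerVector(walk.begin(), walk.end());
    }
  }
  return out;
}

static inline double sigmoid(double x) {
  if (x > 12.0) return 1.0;
  if (x < -12.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling over a walk corpus.
// Negatives drawn proportional to count^0.75; learning rate decays linearly
// from lr_init to lr_final over all (epoch, token) steps.
// Returns the n x d matrix of center vectors.
// [[Rcpp::export]]
NumericMatrix cpp_sgns_train(List walks, int n, int d, int window,
                             int negatives, int epochs,
                             double lr_init, double lr_final) {
  int n_walks = walks.size();
  std::vector<std::vector<int>> corpus(n_walks);
  long long total_tokens = 0;
  std::vector<double> cnt(n, 0.0);
  for (int i = 0; i < n_walks; ++i) {
    IntegerVector wv = walks[i];
    corpus[i] = std::vector<int>(wv.begin(), wv.end());
    total_tokens += wv.size();
    for (int k = 0; k < wv.size(); ++k) cnt[wv[k]] += 1.0;
  }
  // negative-sampling cumulative table
  std::vector<double> cum(n);
  double tot = 0.0;
  for (int i = 0; i < n; ++i) {
    tot += std::pow(cnt[i], 0.75);
    cum[i] = tot;
  }
  // init: centers uniform in [-0.5/d, 0.5/d], contexts zero (word2vec style)
  NumericMatrix U(n, d);
  std::vector<double> V((size_t)n * d, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k)
      U(i, k) = (unif_rand() - 0.5) / d;

  double steps_total = (double)total_tokens * epochs;
  double step = 0.0;
  std::vector<double> grad(d);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int widx = 0; widx < n_walks; ++widx) {
      const std::vector<int> &walk = corpus[widx];
      int L = walk.size();
      for (int c = 0; c < L; ++c) {
        double lr = lr_init + (lr_final - lr_init) * (step / steps_total);
        step += 1.0;
        int center = walk[c];
        int lo = std::max(0, c - window);
        int hi = std::min(L - 1, c + window);
        for (int cx = lo; cx <= hi; ++cx) {
          if (cx == c) continue;
          int context = walk[cx];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negatives; ++neg) {
            int target;
            double label;
            if (neg == 0) {
              target = context;
              label = 1.0;
            } else {
              double u = unif_rand() * tot;
              target = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
              if (target >= n) target = n - 1;
              if (target == context) continue;
              label = 0.0;
            }
            double *vt = &V[(size_t)target * d];
            double dot = 0.0;
            for (int k = 0; k < d; ++k) dot += U(center, k) * vt[k];
            double g = (label - sigmoid(dot)) * lr;
            for (int k = 0; k < d; ++k) {
              grad[k] += g * vt[k];
              vt[k] += g * U(center, k);
            }
          }
          for (int k = 0; k < d; ++k) U(center, k) += grad[k];
        }
      }
    }
  }
  return U;
}

// splitmix64-style mix of (seed, k), reduced to a nonnegative 31-bit int;
// used to derive independent per-run / per-call seeds.
// [[Rcpp::export]]
int cpp_mix_seed(int seed, int k) {
  uint64_t z = (uint64_t)(uint32_t)seed * 0x9E3779B97F4A7C15ULL
             + (uint64_t)(uint32_t)k + 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  z = z ^ (z >> 31);
  return (int)(z & 0x7FFFFFFFULL);
}

// deterministic uniform(0,1) hash of (seed, i, j); the random-score baseline
// [[Rcpp::export]]
NumericVector cpp_hash_scores(IntegerVector i, IntegerVector j, int seed) {
  int n = i.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    uint64_t z = (uint64_t)(uint32_t)seed;
    z ^= (uint64_t)(uint32_t)i[k] * 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z ^= (uint64_t)(uint32_t)j[k] * 0xD1B54A32D192ED03ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    z = z ^ (z >> 31);
    out[k] = (double)(z & 0x1FFFFFFFFFFFFFULL) / (double)0x20000000000000ULL;
  }
  return out;
}
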