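#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Skip-gram with negative sampling over walk corpora (word2vec-style SGD).
// Single-threaded and driven by its own xorshift-free mt19937 stream, so a
// fixed seed reproduces the embedding matrix bit for bit.  Negative targets
// are drawn from a unigram^0.75 table; when `group` assigns vocabulary
// entries to coarse type groups, negatives are drawn from the group of the
// output node (the heterogeneous variant).

static inline double next_unif(std::uint32_t &s) {
  // xorshift32; enough for sampling decisions, independent of libc
  s ^= s << 13; s ^= s >> 17; s ^= s << 5;
  return (double)s / 4294967296.0;
}

// [[Rcpp::export(name = ".sg_train")]]
List sg_train(List sentences, NumericVector counts, int dim,
                       int window, int negative, int epochs, double alpha,
                       IntegerVector group, int seed) {
  const int V = counts.size();
  std::uint32_t rng = (std::uint32_t)seed * 2654435761u + 1u;

  int n_groups = 0;
  for (int i = 0; i < V; ++i) if (group[i] + 1 > n_groups) n_groups = group[i] + 1;

  // per-group cumulative unigram^0.75 tables
  std::vector<std::vector<int> > gids(n_groups);
  std::vector<std::vector<double> > gcum(n_groups);
  for (int g = 0; g < n_groups; ++g) {
    double tot = 0.0;
    for (int i = 0; i < V; ++i) if (group[i] == g) {
      gids[g].push_back(i);
      tot += std::pow((double)counts[i], 0.75);
      gcum[g].push_back(tot);
    }
  }

  NumericMatrix syn0(V, dim);
  NumericMatrix syn1m(V, dim);
  std::vector<double> syn1((size_t)V * dim, 0.0);
  for (int i = 0; i < V; ++i)
    for (int d = 0; d < dim; ++d)
      syn0(i, d) = (next_unif(rng) - 0.5) / dim;

  long long total_words = 0;
  for (int s = 0; s < sentences.size(); ++s)
    total_words += Rf_length(VECTOR_ELT(sentences, s));
  total_words *= (long long)epochs;

  const double min_alpha = alpha * 1e-4;
  long long processed = 0;
  std::vector<double> neu1e(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < sentences.size(); ++s) {
      IntegerVector sent = sentences[s];
      const int n = sent.size();
      for (int t = 0; t < n; ++t) {
        ++processed;
        double lr = alpha * (1.0 - (double)processed / (double)(total_words + 1));
        if (lr < min_alpha) lr = min_alpha;
        int b = (int)(next_unif(rng) * window); // dynamic window shrink
        int w = sent[t];
        for (int c = t - window + b; c <= t + window - b; ++c) {
          if (c == t || c < 0 || c >= n) continue;
          int u = sent[c];           // input (context) node
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target; double label;
            if (d == 0) { target = w; label = 1.0; }
            else {
              int g = group[w];
              double r = next_unif(rng) * gcum[g].back();
              int lo = 0, hi = (int)gcum[g].size() - 1;
              while (lo < hi) {
                int mid = (lo + hi) / 2;
                if (gcum[g][mid] < r) lo = mid + 1; else hi = mid;
              }
              target = gids[g][lo];
              if (target == w) continue;
              label = 0.0;
            }
            double f = 0.0;
            double *o = &syn1[(size_t)target * dim];
            for (int k = 0; k < dim; ++k) f += syn0(u, k) * o[k];
            double sig = 1.0 / (1.0 + std::exp(-f));
            double gderiv = (label - sig) * lr;
            for (int k = 0; k < dim; ++k) {
              neu1e[k] += gderiv * o[k];
              o[k] += gderiv * syn0(u, k);
            }
          }
          for (int k = 0; k < dim; ++k) syn0(u, k) += neu1e[k];
        }
      }
    }
  }
  for (int i = 0; i < V; ++i)
    for (int d = 0; d < dim; ++d)
      syn1m(i, d) = syn1[(size_t)i * dim + d];
  return List::create(Named("input") = syn0, Named("output") = syn1m);
}
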