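#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Skip-gram embedding with negative sampling, trained by plain SGD over
// co-occurrence pairs extracted from random-walk sequences.
//
// Single-threaded on purpose: all randomness flows through R's RNG
// (unif_rand), so a set.seed() on the R side gives bitwise-reproducible
// embeddings. Negative samples are drawn from the unigram distribution
// raised to the 3/4 power, the standard choice for this family of models.
//
// walks: list of 1-based integer vectors. Returns the n_nodes x dim matrix
// of input (center) vectors.

static inline double sigmoid_clip(double x) {
  if (x > 8.0) return 1.0 - 1e-8;
  if (x < -8.0) return 1e-8;
  return 1.0 / (1.0 + std::exp(-x));
}

// [[Rcpp::export]]
NumericMatrix sgd_skipgram(List walks, int n_nodes, int dim, int window,
                           int negatives, int epochs, double lr) {
  RNGScope scope;

  // unigram^{3/4} cumulative table for negative sampling
  std::vector<double> freq(n_nodes, 0.0);
  for (int w = 0; w < walks.size(); ++w) {
    IntegerVector wk = walks[w];
    for (int t = 0; t < wk.size(); ++t) freq[wk[t] - 1] += 1.0;
  }
  std::vector<double> cum(n_nodes, 0.0);
  double tot = 0.0;
  for (int v = 0; v < n_nodes; ++v) {
    tot += (freq[v] > 0.0) ? std::pow(freq[v], 0.75) : 0.0;
    cum[v] = tot;
  }
  if (tot <= 0.0) stop("no training pairs: all walks are empty");
  for (int v = 0; v < n_nodes; ++v) cum[v] /= tot;

  // init in (-0.5/dim, 0.5/dim), contexts at zero
  std::vector<double> f((size_t)n_nodes * dim), g((size_t)n_nodes * dim, 0.0);
  for (size_t z = 0; z < f.size(); ++z) f[z] = (unif_rand() - 0.5) / dim;

  // total update count for linear learning-rate decay
  long total_pairs = 0;
  for (int w = 0; w < walks.size(); ++w) {
    IntegerVector wk = walks[w];
    int len = wk.size();
    for (int t = 0; t < len; ++t) {
      int lo = std::max(0, t - window), hi = std::min(len - 1, t + window);
      total_pairs += (hi - lo); // excludes the center itself
    }
  }
  total_pairs *= epochs;
  if (total_pairs == 0) stop("no training pairs: walks too short for the window");

  // materialize walks once (0-based) so the hot loop avoids SEXP accessors
  std::vector<std::vector<int> > wks(walks.size());
  for (int w = 0; w < walks.size(); ++w) {
    IntegerVector wk = walks[w];
    wks[w].resize(wk.size());
    for (int t = 0; t < wk.size(); ++t) wks[w][t] = wk[t] - 1;
  }

  std::vector<double> grad(dim);
  long done = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (size_t w = 0; w < wks.size(); ++w) {
      const std::vector<int> &wk = wks[w];
      int len = (int)wk.size();
      for (int t = 0; t < len; ++t) {
        int c = wk[t];
        double * __restrict__ fc = &f[(size_t)c * dim];
        int lo = std::max(0, t - window), hi = std::min(len - 1, t + window);
        for (int u = lo; u <= hi; ++u) {
          if (u == t) continue;
          double alpha = lr * std::max(1e-4, 1.0 - (double)done / total_pairs);
          ++done;
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int s = 0; s < negatives + 1; ++s) {
            int target;
            double label;
            if (s == 0) { target = wk[u]; label = 1.0; }
            else {
              double r = unif_rand();
              target = (int)(std::lower_bound(cum.begin(), cum.end(), r) - cum.begin());
              if (target >= n_nodes) target = n_nodes - 1;
              label = 0.0;
              if (target == c) continue;
            }
            double * __restrict__ gt = &g[(size_t)target * dim];
            double dot = 0.0;
            for (int z = 0; z < dim; ++z) dot += fc[z] * gt[z];
            double err = (label - sigmoid_clip(dot)) * alpha;
            for (int z = 0; z < dim; ++z) {
              grad[z] += err * gt[z];
              gt[z] += err * fc[z];
            }
          }
          for (int z = 0; z < dim; ++z) fc[z] += grad[z];
        }
      }
    }
  }

  NumericMatrix out(n_nodes, dim);
  for (int v = 0; v < n_nodes; ++v)
    for (int z = 0; z < dim; ++z) out(v, z) = f[(size_t)v * dim + z];
  return out;
}
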