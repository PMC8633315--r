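#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Deterministic 64-bit RNG (splitmix64) so layouts are bit-identical for a
// given seed across platforms, independent of R's RNG state.
static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97f4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double clip4(double x) {
  if (x > 4.0) return 4.0;
  if (x < -4.0) return -4.0;
  return x;
}

// Stochastic gradient optimization of a low-dimensional layout against a
// fuzzy neighbor graph: attractive updates along sampled edges, repulsive
// updates against uniformly sampled vertices (negative sampling), with the
// standard 1/(1 + a d^{2b}) low-dimensional similarity kernel.
// head/tail are 0-based vertex indices per directed edge.
// [[Rcpp::export]]
NumericMatrix optimize_layout(NumericMatrix init, IntegerVector head,
                              IntegerVector tail,
                              NumericVector epochs_per_sample, double a,
                              double b, int n_epochs, double initial_alpha,
                              double negative_sample_rate, int seed) {
  NumericMatrix emb = clone(init);
  const int n_vertices = emb.nrow();
  const int dim = emb.ncol();
  const int n_edges = head.size();
  std::vector<double> next_sample(n_edges), next_neg(n_edges),
      eps_per_neg(n_edges);
  for (int i = 0; i < n_edges; i++) {
    next_sample[i] = epochs_per_sample[i];
    eps_per_neg[i] = epochs_per_sample[i] / negative_sample_rate;
    next_neg[i] = eps_per_neg[i];
  }
  uint64_t rng_state = 0x853C49E6748FEA9BULL ^ (uint64_t)seed;

  for (int epoch = 1; epoch <= n_epochs; epoch++) {
    double alpha = initial_alpha * (1.0 - (double)epoch / (double)n_epochs);
    for (int i = 0; i < n_edges; i++) {
      if (next_sample[i] > epoch) continue;
      int j = head[i], l = tail[i];
      double d2 = 0;
      for (int d = 0; d < dim; d++) {
        double diff = emb(j, d) - emb(l, d);
        d2 += diff * diff;
      }
      if (d2 > 0) {
        double coeff = (-2.0 * a * b * std::pow(d2, b - 1.0)) /
                       (a * std::pow(d2, b) + 1.0);
        for (int d = 0; d < dim; d++) {
          double g = clip4(coeff * (emb(j, d) - emb(l, d))) * alpha;
          emb(j, d) += g;
          emb(l, d) -= g;
        }
      }
      next_sample[i] += epochs_per_sample[i];

      int n_neg = (int)((epoch - next_neg[i]) / eps_per_neg[i]) + 1;
      for (int p = 0; p < n_neg; p++) {
        int m = (int)(splitmix64(rng_state) % (uint64_t)n_vertices);
        if (m == j) continue;
        double d2n = 0;
        for (int d = 0; d < dim; d++) {
          double diff = emb(j, d) - emb(m, d);
          d2n += diff * diff;
        }
        double coeff =
            (2.0 * b) / ((0.001 + d2n) * (a * std::pow(d2n, b) + 1.0));
        for (int d = 0; d < dim; d++) {
          double g;
          if (coeff > 0) {
            g = clip4(coeff * (emb(j, d) - emb(m, d)));
          } else {
            g = 4.0;
          }
          emb(j, d) += g * alpha;
        }
      }
      next_neg[i] += n_neg * eps_per_neg[i];
    }
  }
  return emb;
}
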