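#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Skip-gram with negative sampling, single-threaded SGD with a linearly
// decaying learning rate, negatives drawn from the unigram^0.75
// distribution, and word2vec-style frequency subsampling. Uses R's RNG so
// training is reproducible via set.seed().

static inline double sigmoid(double x) {
  if (x > 12.0) return 1.0;
  if (x < -12.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// [[Rcpp::export]]
List sgns_train_cpp(List docs, NumericVector counts, int dim, int window,
                    int negative, int epochs, double alpha0,
                    double subsample) {
  int V = counts.size();
  int N = docs.size();

  // cumulative unigram^0.75 table for negative sampling (binary search)
  std::vector<double> cum(V);
  double Z = 0.0;
  for (int v = 0; v < V; ++v) {
    Z += std::pow(counts[v], 0.75);
    cum[v] = Z;
  }

  double total_tokens = 0.0;
  for (int d = 0; d < N; ++d) total_tokens += ((IntegerVector)docs[d]).size();

  // subsampling keep-probabilities
  std::vector<double> keep(V, 1.0);
  if (subsample > 0) {
    double T = 0.0;
    for (int v = 0; v < V; ++v) T += counts[v];
    for (int v = 0; v < V; ++v) {
      double f = counts[v] / T;
      if (f > subsample) {
        double p = (std::sqrt(f / subsample) + 1.0) * subsample / f;
        keep[v] = p < 1.0 ? p : 1.0;
      }
    }
  }

  NumericMatrix syn0(V, dim), syn1(V, dim);
  for (int v = 0; v < V; ++v)
    for (int j = 0; j < dim; ++j)
      syn0(v, j) = (unif_rand() - 0.5) / dim;

  NumericVector epoch_loss(epochs);
  std::vector<double> grad(dim);
  double processed = 0.0;
  double denom_tokens = total_tokens * epochs;
  std::vector<int> sen;
  sen.reserve(256);

  for (int ep = 0; ep < epochs; ++ep) {
    double loss = 0.0;
    long n_pairs = 0;
    for (int d = 0; d < N; ++d) {
      IntegerVector dv = docs[d];
      sen.clear();
      for (int i = 0; i < dv.size(); ++i) {
        processed += 1.0;
        int w = dv[i];
        if (keep[w] < 1.0 && unif_rand() > keep[w]) continue;
        sen.push_back(w);
      }
      int L = (int)sen.size();
      for (int i = 0; i < L; ++i) {
        int center = sen[i];
        double alpha = alpha0 * (1.0 - processed / denom_tokens);
        if (alpha < alpha0 * 1e-4) alpha = alpha0 * 1e-4;
        int b = 1 + (int)(unif_rand() * window); // dynamic window size
        if (b > window) b = window;
        for (int off = -b; off <= b; ++off) {
          if (off == 0) continue;
          int j = i + off;
          if (j < 0 || j >= L) continue;
          int context = sen[j];
          // one positive + `negative` sampled targets against syn1
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int s = 0; s <= negative; ++s) {
            int target;
            double label;
            if (s == 0) {
              target = context;
              label = 1.0;
            } else {
              double u = unif_rand() * Z;
              target = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
              if (target >= V) target = V - 1;
              if (target == context) continue;
              label = 0.0;
            }
            double dot = 0.0;
            for (int c = 0; c < dim; ++c) dot += syn0(center, c) * syn1(target, c);
            double pred = sigmoid(dot);
            double g = (label - pred) * alpha;
            loss -= label > 0.5 ? std::log(pred + 1e-12) : std::log(1.0 - pred + 1e-12);
            for (int c = 0; c < dim; ++c) {
              grad[c] += g * syn1(target, c);
              syn1(target, c) += g * syn0(center, c);
            }
          }
          for (int c = 0; c < dim; ++c) syn0(center, c) += grad[c];
          n_pairs++;
        }
      }
      if (d % 200 == 0) Rcpp::checkUserInterrupt();
    }
    epoch_loss[ep] = n_pairs > 0 ? loss / n_pairs : NA_REAL;
  }

  return List::create(_["vectors"] = syn0, _["context_vectors"] = syn1,
                      _["epoch_loss"] = epoch_loss);
}
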