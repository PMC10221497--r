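#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation.
// docs: list of 0-based word-index vectors. Topic-word and doc-topic counts
// are averaged over post-burn-in sweeps; the caller adds Dirichlet smoothing
// and normalizes. Uses R's RNG so results are reproducible via set.seed().

static inline int sample_discrete(const std::vector<double> &p, double total) {
  double u = unif_rand() * total;
  double acc = 0.0;
  int K = (int)p.size();
  for (int k = 0; k < K; ++k) {
    acc += p[k];
    if (u <= acc) return k;
  }
  return K - 1;
}

// [[Rcpp::export]]
List lda_gibbs_cpp(List docs, int V, int K, double alpha, double beta,
                   int n_iter, int burn_in) {
  int N = docs.size();
  std::vector<std::vector<int> > w(N), z(N);
  for (int d = 0; d < N; ++d) {
    IntegerVector dv = docs[d];
    w[d].assign(dv.begin(), dv.end());
    z[d].resize(dv.size());
  }

  std::vector<int> nkw((size_t)K * V, 0), nk(K, 0);
  std::vector<std::vector<int> > ndk(N, std::vector<int>(K, 0));

  // random initial assignments
  for (int d = 0; d < N; ++d) {
    for (size_t i = 0; i < w[d].size(); ++i) {
      int k = (int)(unif_rand() * K);
      if (k == K) k = K - 1;
      z[d][i] = k;
      ndk[d][k]++;
      nkw[(size_t)k * V + w[d][i]]++;
      nk[k]++;
    }
  }

  std::vector<double> avg_nkw((size_t)K * V, 0.0);
  std::vector<std::vector<double> > avg_ndk(N, std::vector<double>(K, 0.0));
  int n_kept = 0;
  double Vbeta = V * beta;
  std::vector<double> p(K);

  for (int it = 0; it < n_iter; ++it) {
    for (int d = 0; d < N; ++d) {
      for (size_t i = 0; i < w[d].size(); ++i) {
        int word = w[d][i];
        int old = z[d][i];
        ndk[d][old]--;
        nkw[(size_t)old * V + word]--;
        nk[old]--;
        double total = 0.0;
        for (int k = 0; k < K; ++k) {
          double pk = (ndk[d][k] + alpha) *
                      (nkw[(size_t)k * V + word] + beta) / (nk[k] + Vbeta);
          p[k] = pk;
          total += pk;
        }
        int knew = sample_discrete(p, total);
        z[d][i] = knew;
        ndk[d][knew]++;
        nkw[(size_t)knew * V + word]++;
        nk[knew]++;
      }
    }
    if (it >= burn_in) {
      n_kept++;
      for (size_t j = 0; j < avg_nkw.size(); ++j) avg_nkw[j] += nkw[j];
      for (int d = 0; d < N; ++d)
        for (int k = 0; k < K; ++k) avg_ndk[d][k] += ndk[d][k];
    }
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
  }
  if (n_kept == 0) n_kept = 1;

  NumericMatrix topic_word(K, V);
  for (int k = 0; k < K; ++k)
    for (int v = 0; v < V; ++v)
      topic_word(k, v) = avg_nkw[(size_t)k * V + v] / n_kept;
  NumericMatrix doc_topic(N, K);
  for (int d = 0; d < N; ++d)
    for (int k = 0; k < K; ++k)
      doc_topic(d, k) = avg_ndk[d][k] / n_kept;

  List zs(N);
  for (int d = 0; d < N; ++d) zs[d] = IntegerVector(z[d].begin(), z[d].end());

  return List::create(_["topic_word_counts"] = topic_word,
                      _["doc_topic_counts"] = doc_topic,
                      _["assignments"] = zs);
}

// Fold-in scoring of held-out documents: Gibbs-sample token assignments with
// the topic-word distribution phi (K x V, rows sum to 1) held fixed.
// [[Rcpp::export]]
NumericMatrix lda_fold_in_cpp(List docs, NumericMatrix phi, double alpha,
                              int n_iter, int burn_in) {
  int K = phi.nrow();
  int N = docs.size();
  NumericMatrix out(N, K);
  std::vector<double> p(K);

  for (int d = 0; d < N; ++d) {
    IntegerVector dv = docs[d];
    int L = dv.size();
    if (L == 0) {
      for (int k = 0; k < K; ++k) out(d, k) = 1.0 / K;
      continue;
    }
    std::vector<int> zd(L);
    std::vector<int> nd(K, 0);
    for (int i = 0; i < L; ++i) {
      int k = (int)(unif_rand() * K);
      if (k == K) k = K - 1;
      zd[i] = k;
      nd[k]++;
    }
    std::vector<double> acc(K, 0.0);
    int kept = 0;
    for (int it = 0; it < n_iter; ++it) {
      for (int i = 0; i < L; ++i) {
        int word = dv[i];
        nd[zd[i]]--;
        double total = 0.0;
        for (int k = 0; k < K; ++k) {
          double pk = (nd[k] + alpha) * phi(k, word);
          p[k] = pk;
          total += pk;
        }
        int knew = sample_discrete(p, total);
        zd[i] = knew;
        nd[knew]++;
      }
      if (it >= burn_in) {
        kept++;
        for (int k = 0; k < K; ++k) acc[k] += nd[k];
      }
    }
    double denom = (double)kept * L + K * alpha * kept;
    for (int k = 0; k < K; ++k)
      out(d, k) = (acc[k] + alpha * kept) / denom;
  }
  return out;
}
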