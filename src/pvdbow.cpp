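#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Deterministic internal RNG (xorshift64*), independent of R's RNG so that
// training and inference are reproducible across platforms given a seed.
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(unif() * n); }
};

static inline double sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// cumulative unigram^pow table for negative sampling
static std::vector<double> unigram_cdf(const NumericVector& counts, double pw) {
  std::vector<double> cdf(counts.size());
  double tot = 0.0;
  for (int i = 0; i < counts.size(); ++i) {
    tot += std::pow((double)counts[i], pw);
    cdf[i] = tot;
  }
  for (size_t i = 0; i < cdf.size(); ++i) cdf[i] /= tot;
  return cdf;
}

static inline int sample_word(const std::vector<double>& cdf, XorShift& rng) {
  double u = rng.unif();
  return (int)(std::upper_bound(cdf.begin(), cdf.end(), u) - cdf.begin());
}

// One negative-sampling update of a document vector against target word w.
// Updates doc in place; updates word matrix only when train_words is true.
static inline void ns_update(double* doc, double* word, int dim, int w,
                             int negative, double alpha,
                             const std::vector<double>& cdf, XorShift& rng,
                             std::vector<double>& neu1e, bool train_words) {
  std::fill(neu1e.begin(), neu1e.end(), 0.0);
  for (int s = 0; s <= negative; ++s) {
    int target; double label;
    if (s == 0) { target = w; label = 1.0; }
    else {
      target = sample_word(cdf, rng);
      if (target == w) continue;
      label = 0.0;
    }
    double* wv = word + (size_t)target * dim;
    double f = 0.0;
    for (int k = 0; k < dim; ++k) f += doc[k] * wv[k];
    double g = (label - sigmoid(f)) * alpha;
    for (int k = 0; k < dim; ++k) neu1e[k] += g * wv[k];
    if (train_words) for (int k = 0; k < dim; ++k) wv[k] += g * doc[k];
  }
  for (int k = 0; k < dim; ++k) doc[k] += neu1e[k];
}

// [[Rcpp::export]]
List cpp_pvdbow_train(List docs, NumericVector counts, int dim, int epochs,
                      double alpha0, double decay, double min_alpha,
                      int negative, double unigram_pow, double seed) {
  int n_docs = docs.size();
  int vocab = counts.size();
  XorShift rng((uint64_t)seed);
  std::vector<double> cdf = unigram_cdf(counts, unigram_pow);

  NumericMatrix doc_mat(dim, n_docs);   // column-major: one doc per column
  NumericMatrix word_mat(dim, vocab);
  double span = 1.0 / dim;
  for (int j = 0; j < n_docs; ++j)
    for (int k = 0; k < dim; ++k)
      doc_mat(k, j) = (rng.unif() - 0.5) * span;

  std::vector<std::vector<int> > dv(n_docs);
  for (int j = 0; j < n_docs; ++j) {
    IntegerVector t = docs[j];
    dv[j].assign(t.begin(), t.end());
  }

  std::vector<double> neu1e(dim);
  for (int e = 0; e < epochs; ++e) {
    double alpha = std::max(alpha0 - e * decay, min_alpha);
    for (int j = 0; j < n_docs; ++j) {
      double* doc = &doc_mat(0, j);
      const std::vector<int>& toks = dv[j];
      for (size_t t = 0; t < toks.size(); ++t)
        ns_update(doc, &word_mat(0, 0), dim, toks[t], negative, alpha,
                  cdf, rng, neu1e, true);
    }
  }
  return List::create(_["doc"] = doc_mat, _["word"] = word_mat);
}

// [[Rcpp::export]]
NumericVector cpp_pvdbow_infer(IntegerVector tokens, NumericMatrix word_mat,
                               NumericVector counts, int epochs,
                               double alpha0, double decay, double min_alpha,
                               int negative, double unigram_pow, double seed) {
  int dim = word_mat.nrow();
  XorShift rng((uint64_t)seed);
  std::vector<double> cdf = unigram_cdf(counts, unigram_pow);
  NumericVector doc(dim);
  double span = 1.0 / dim;
  for (int k = 0; k < dim; ++k) doc[k] = (rng.unif() - 0.5) * span;
  std::vector<double> neu1e(dim);
  for (int e = 0; e < epochs; ++e) {
    double alpha = std::max(alpha0 - e * decay, min_alpha);
    for (int t = 0; t < tokens.size(); ++t)
      ns_update(&doc[0], &word_mat(0, 0), dim, tokens[t], negative, alpha,
                cdf, rng, neu1e, false);
  }
  return doc;
}
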