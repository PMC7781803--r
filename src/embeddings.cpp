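// Skip-gram negative-sampling word embeddings and distributed bag-of-words
// document embeddings. Single-threaded with an explicit RNG seed so training
// is bit-reproducible; corpora here are ward-scale, not web-scale.
// Vector matrices are stored one column per token/document (column-major
// contiguity for the inner update loops); the R wrappers transpose.
#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

namespace {

inline double sigmoid(double x) {
  if (x > 12.0) return 1.0;
  if (x < -12.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// cumulative unigram^0.75 table for negative sampling
std::vector<double> neg_table(const NumericVector& counts) {
  std::vector<double> cum(counts.size());
  double tot = 0.0;
  for (int i = 0; i < counts.size(); ++i) {
    tot += std::pow((double)counts[i], 0.75);
    cum[i] = tot;
  }
  return cum;
}

inline int sample_neg(const std::vector<double>& cum, std::mt19937_64& rng) {
  std::uniform_real_distribution<double> unif(0.0, cum.back());
  double u = unif(rng);
  return (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
}

// one SGNS update: input vector (contiguous, length dim) against the
// positive target column of syn1 plus `negative` sampled negatives
inline void sgns_pair(double* in_vec, NumericMatrix& syn1, int pos_target,
                      int dim, int negative, double lr,
                      const std::vector<double>& cum, std::mt19937_64& rng,
                      std::vector<double>& err) {
  std::fill(err.begin(), err.end(), 0.0);
  for (int d = 0; d <= negative; ++d) {
    int target;
    double label;
    if (d == 0) {
      target = pos_target;
      label = 1.0;
    } else {
      target = sample_neg(cum, rng);
      if (target == pos_target) continue;
      label = 0.0;
    }
    double* out_vec = &syn1(0, target);
    double f = 0.0;
    for (int k = 0; k < dim; ++k) f += in_vec[k] * out_vec[k];
    double g = (label - sigmoid(f)) * lr;
    for (int k = 0; k < dim; ++k) {
      err[k] += g * out_vec[k];
      out_vec[k] += g * in_vec[k];
    }
  }
  for (int k = 0; k < dim; ++k) in_vec[k] += err[k];
}

} // namespace

// [[Rcpp::export]]
List cpp_sgns_train(List sentences, int vocab_size, int dim, int window,
                    int negative, int epochs, double alpha,
                    NumericVector counts, int seed) {
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(-0.5 / dim, 0.5 / dim);
  NumericMatrix syn0(dim, vocab_size), syn1(dim, vocab_size);
  for (int i = 0; i < vocab_size; ++i)
    for (int k = 0; k < dim; ++k) syn0(k, i) = unif(rng);
  std::vector<double> cum = neg_table(counts);
  std::vector<double> err(dim);

  long long total = 0;
  for (int s = 0; s < sentences.size(); ++s)
    total += ((IntegerVector)sentences[s]).size();
  total *= epochs;
  long long processed = 0;
  const double min_alpha = alpha * 1e-2;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < sentences.size(); ++s) {
      IntegerVector sent = sentences[s];
      int len = sent.size();
      for (int pos = 0; pos < len; ++pos) {
        double lr = alpha * (1.0 - (double)processed / (double)(total + 1));
        if (lr < min_alpha) lr = min_alpha;
        ++processed;
        int w = sent[pos];
        // reduced window as in the reference skip-gram implementation
        int b = (int)(rng() % (uint64_t)window);
        for (int j = pos - window + b; j <= pos + window - b; ++j) {
          if (j == pos || j < 0 || j >= len) continue;
          sgns_pair(&syn0(0, w), syn1, sent[j], dim, negative, lr, cum, rng,
                    err);
        }
      }
    }
  }
  return List::create(_["syn0"] = syn0, _["syn1"] = syn1);
}

// [[Rcpp::export]]
List cpp_pvdbow_train(List sentences, int vocab_size, int dim, int negative,
                      int epochs, double alpha, NumericVector counts,
                      int seed) {
  int n_docs = sentences.size();
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(-0.5 / dim, 0.5 / dim);
  NumericMatrix docvecs(dim, n_docs), syn1(dim, vocab_size);
  for (int i = 0; i < n_docs; ++i)
    for (int k = 0; k < dim; ++k) docvecs(k, i) = unif(rng);
  std::vector<double> cum = neg_table(counts);
  std::vector<double> err(dim);

  long long total = 0;
  for (int s = 0; s < n_docs; ++s)
    total += ((IntegerVector)sentences[s]).size();
  total *= epochs;
  long long processed = 0;
  const double min_alpha = alpha * 1e-2;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_docs; ++s) {
      IntegerVector sent = sentences[s];
      for (int pos = 0; pos < sent.size(); ++pos) {
        double lr = alpha * (1.0 - (double)processed / (double)(total + 1));
        if (lr < min_alpha) lr = min_alpha;
        ++processed;
        sgns_pair(&docvecs(0, s), syn1, sent[pos], dim, negative, lr, cum,
                  rng, err);
      }
    }
  }
  return List::create(_["docvecs"] = docvecs, _["syn1"] = syn1);
}

// [[Rcpp::export]]
NumericVector cpp_pvdbow_infer(IntegerVector sentence, NumericMatrix syn1,
                               int dim, int negative, int epochs,
                               double alpha, NumericVector counts, int seed) {
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(-0.5 / dim, 0.5 / dim);
  NumericVector vec(dim);
  for (int k = 0; k < dim; ++k) vec[k] = unif(rng);
  if (sentence.size() == 0) return vec;
  std::vector<double> cum = neg_table(counts);
  std::vector<double> err(dim);
  long long total = (long long)sentence.size() * epochs;
  long long processed = 0;
  const double min_alpha = alpha * 1e-2;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int pos = 0; pos < sentence.size(); ++pos) {
      double lr = alpha * (1.0 - (double)processed / (double)(total + 1));
      if (lr < min_alpha) lr = min_alpha;
      ++processed;
      int w = sentence[pos];
      std::fill(err.begin(), err.end(), 0.0);
      // output vectors stay frozen: only the document vector moves
      for (int d = 0; d <= negative; ++d) {
        int target;
        double label;
        if (d == 0) {
          target = w;
          label = 1.0;
        } else {
          target = sample_neg(cum, rng);
          if (target == w) continue;
          label = 0.0;
        }
        double f = 0.0;
        for (int k = 0; k < dim; ++k) f += vec[k] * syn1(k, target);
        double g = (label - sigmoid(f)) * lr;
        for (int k = 0; k < dim; ++k) err[k] += g * syn1(k, target);
      }
      for (int k = 0; k < dim; ++k) vec[k] += err[k];
    }
  }
  return vec;
}
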