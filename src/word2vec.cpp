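// Native word2vec-style trainer: CBOW / skip-gram with negative sampling.
// Single-threaded and driven by its own linear congruential generator so a
// given (corpus, hyperparameters, seed) always yields bit-identical vectors,
// independently of R's RNG state and of the platform.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double MAX_EXP = 6.0;

static inline double sigmoid_clipped(double f) {
  if (f > MAX_EXP) return 1.0;
  if (f < -MAX_EXP) return 0.0;
  return 1.0 / (1.0 + std::exp(-f));
}

// java/word2vec-style LCG; 48-bit state in a 64-bit word
static inline unsigned long long lcg_next(unsigned long long s) {
  return s * 25214903917ULL + 11ULL;
}

// [[Rcpp::export]]
NumericMatrix w2v_train_cpp(List sentences, int vocab_size,
                            IntegerVector counts, int dim, int window,
                            int negative, int epochs, double alpha,
                            double min_alpha, bool cbow, double sample,
                            int seed) {
  if (vocab_size <= 0 || dim <= 0) stop("empty vocabulary or dimension");
  unsigned long long rng = (unsigned long long)(unsigned int)seed + 1ULL;

  // unigram table, counts raised to the 3/4 power
  const int table_size = 100000;
  std::vector<int> table(table_size);
  {
    double total = 0.0;
    for (int i = 0; i < vocab_size; i++) total += std::pow((double)counts[i], 0.75);
    int i = 0;
    double cum = std::pow((double)counts[0], 0.75) / total;
    for (int a = 0; a < table_size; a++) {
      table[a] = i;
      if ((double)a / table_size > cum && i < vocab_size - 1) {
        i++;
        cum += std::pow((double)counts[i], 0.75) / total;
      }
    }
  }

  // input vectors initialised uniformly in (-0.5/dim, 0.5/dim); output
  // (negative-sampling) vectors start at zero
  std::vector<double> syn0((size_t)vocab_size * dim);
  std::vector<double> syn1neg((size_t)vocab_size * dim, 0.0);
  for (size_t a = 0; a < syn0.size(); a++) {
    rng = lcg_next(rng);
    syn0[a] = (((rng & 0xFFFF) / 65536.0) - 0.5) / dim;
  }

  long long train_words = 0;
  for (int s = 0; s < sentences.size(); s++)
    train_words += ((IntegerVector)sentences[s]).size();
  if (train_words == 0) stop("corpus contains no tokens");
  const long long total_steps = (long long)epochs * train_words;

  std::vector<double> neu1(dim), neu1e(dim);
  std::vector<int> sen;
  sen.reserve(1024);
  long long words_done = 0;
  double lr = alpha;

  for (int ep = 0; ep < epochs; ep++) {
    for (int s = 0; s < sentences.size(); s++) {
      IntegerVector raw = sentences[s];
      sen.clear();
      for (int t = 0; t < raw.size(); t++) {
        int w = raw[t];
        words_done++;
        if (sample > 0) {  // frequent-word subsampling (off by default here)
          double f = (double)counts[w];
          double thr = sample * train_words;
          double keep = (std::sqrt(f / thr) + 1.0) * thr / f;
          rng = lcg_next(rng);
          if (keep < (rng & 0xFFFF) / 65536.0) continue;
        }
        sen.push_back(w);
      }
      int slen = (int)sen.size();
      if (slen == 0) continue;
      lr = alpha * (1.0 - (double)words_done / (double)(total_steps + 1));
      if (lr < min_alpha) lr = min_alpha;

      for (int pos = 0; pos < slen; pos++) {
        int word = sen[pos];
        rng = lcg_next(rng);
        int b = (int)(rng % (unsigned long long)window);

        if (cbow) {
          std::fill(neu1.begin(), neu1.end(), 0.0);
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          int cw = 0;
          for (int a = b; a < window * 2 + 1 - b; a++) {
            if (a == window) continue;
            int c = pos - window + a;
            if (c < 0 || c >= slen) continue;
            const double* v = &syn0[(size_t)sen[c] * dim];
            for (int d = 0; d < dim; d++) neu1[d] += v[d];
            cw++;
          }
          if (cw == 0) continue;
          for (int d = 0; d < dim; d++) neu1[d] /= cw;
          for (int n = 0; n <= negative; n++) {
            int target; double label;
            if (n == 0) { target = word; label = 1.0; }
            else {
              rng = lcg_next(rng);
              target = table[(rng >> 16) % table_size];
              if (target == word) continue;
              label = 0.0;
            }
            double* out = &syn1neg[(size_t)target * dim];
            double f = 0.0;
            for (int d = 0; d < dim; d++) f += neu1[d] * out[d];
            double g = (label - sigmoid_clipped(f)) * lr;
            for (int d = 0; d < dim; d++) neu1e[d] += g * out[d];
            for (int d = 0; d < dim; d++) out[d] += g * neu1[d];
          }
          for (int a = b; a < window * 2 + 1 - b; a++) {
            if (a == window) continue;
            int c = pos - window + a;
            if (c < 0 || c >= slen) continue;
            double* v = &syn0[(size_t)sen[c] * dim];
            for (int d = 0; d < dim; d++) v[d] += neu1e[d];
          }
        } else {  // skip-gram: each context word predicts the centre word
          for (int a = b; a < window * 2 + 1 - b; a++) {
            if (a == window) continue;
            int c = pos - window + a;
            if (c < 0 || c >= slen) continue;
            double* in = &syn0[(size_t)sen[c] * dim];
            std::fill(neu1e.begin(), neu1e.end(), 0.0);
            for (int n = 0; n <= negative; n++) {
              int target; double label;
              if (n == 0) { target = word; label = 1.0; }
              else {
                rng = lcg_next(rng);
                target = table[(rng >> 16) % table_size];
                if (target == word) continue;
                label = 0.0;
              }
              double* out = &syn1neg[(size_t)target * dim];
              double f = 0.0;
              for (int d = 0; d < dim; d++) f += in[d] * out[d];
              double g = (label - sigmoid_clipped(f)) * lr;
              for (int d = 0; d < dim; d++) neu1e[d] += g * out[d];
              for (int d = 0; d < dim; d++) out[d] += g * in[d];
            }
            for (int d = 0; d < dim; d++) in[d] += neu1e[d];
          }
        }
      }
    }
  }

  NumericMatrix res(vocab_size, dim);
  for (int i = 0; i < vocab_size; i++)
    for (int d = 0; d < dim; d++) res(i, d) = syn0[(size_t)i * dim + d];
  return res;
}
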