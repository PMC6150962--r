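#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Deterministic single-thread skip-gram with negative sampling over walk
// corpora. A private xorshift RNG (not R's) keeps training byte-reproducible
// for a given seed regardless of the caller's RNG state.

namespace {

struct XorShift64 {
  uint64_t s;
  explicit XorShift64(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  // uniform in [0, n)
  uint64_t next_below(uint64_t n) { return next() % n; }
  double next_unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

} // namespace

// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train(List walks, int vocab_size, int dim, int window,
                         int negative, int epochs, double alpha, int seed) {
  const int V = vocab_size, D = dim;
  if (V < 1 || D < 1) stop("vocabulary and dimension must be positive");

  // token counts -> unigram^(3/4) negative-sampling table
  std::vector<double> cnt(V, 0.0);
  long long total_tokens = 0;
  const int n_walks = walks.size();
  std::vector<std::vector<int>> corpus(n_walks);
  for (int w = 0; w < n_walks; ++w) {
    IntegerVector wk = walks[w];
    corpus[w].assign(wk.begin(), wk.end());
    for (int tok : corpus[w]) {
      if (tok < 0 || tok >= V) stop("walk token out of range");
      cnt[tok] += 1.0;
      ++total_tokens;
    }
  }
  if (total_tokens == 0) stop("empty walk corpus");

  const int TABLE = 1 << 17;
  std::vector<int> neg_table(TABLE);
  {
    double z = 0.0;
    for (int i = 0; i < V; ++i) z += std::pow(cnt[i], 0.75);
    double cum = std::pow(cnt[0], 0.75) / z;
    int i = 0;
    for (int a = 0; a < TABLE; ++a) {
      neg_table[a] = i;
      if ((a + 1.0) / TABLE > cum && i < V - 1) {
        ++i;
        cum += std::pow(cnt[i], 0.75) / z;
      }
    }
  }

  XorShift64 rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);

  std::vector<double> syn0(static_cast<size_t>(V) * D);
  std::vector<double> syn1(static_cast<size_t>(V) * D, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.next_unif() - 0.5) / D;

  const double alpha_min = alpha * 1e-4;
  const long long steps_total =
      static_cast<long long>(epochs) * total_tokens;
  long long steps_done = 0;
  std::vector<double> grad(D);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int w = 0; w < n_walks; ++w) {
      const std::vector<int>& wk = corpus[w];
      const int L = static_cast<int>(wk.size());
      for (int pos = 0; pos < L; ++pos) {
        double lr = alpha * (1.0 - static_cast<double>(steps_done) / steps_total);
        if (lr < alpha_min) lr = alpha_min;
        ++steps_done;
        // dynamic window shrink, word2vec convention
        int b = static_cast<int>(rng.next_below(static_cast<uint64_t>(window)));
        int center = wk[pos];
        for (int off = b - window; off <= window - b; ++off) {
          if (off == 0) continue;
          int cpos = pos + off;
          if (cpos < 0 || cpos >= L) continue;
          int context = wk[cpos];
          double* v_in = &syn0[static_cast<size_t>(context) * D];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int target; double label;
            if (neg == 0) { target = center; label = 1.0; }
            else {
              target = neg_table[rng.next_below(TABLE)];
              if (target == center) continue;
              label = 0.0;
            }
            double* v_out = &syn1[static_cast<size_t>(target) * D];
            double dot = 0.0;
            for (int d = 0; d < D; ++d) dot += v_in[d] * v_out[d];
            double g = (label - sigmoid(dot)) * lr;
            for (int d = 0; d < D; ++d) {
              grad[d] += g * v_out[d];
              v_out[d] += g * v_in[d];
            }
          }
          for (int d = 0; d < D; ++d) v_in[d] += grad[d];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(V, D);
  for (int i = 0; i < V; ++i)
    for (int d = 0; d < D; ++d)
      out(i, d) = syn0[static_cast<size_t>(i) * D + d];
  return out;
}
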