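#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// xorshift64* generator: all compiled-path randomness (walks, negative
// sampling) goes through this so results are bit-reproducible for a given
// seed and independent of R's RNG state.
struct XRng {
  uint64_t s;
  explicit XRng(double seed) {
    s = (uint64_t)seed;
    s = s * 6364136223846793005ULL + 1442695040888963407ULL;
    if (s == 0) s = 0x9E3779B97F4A7C15ULL;
  }
  uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

// Pairwise Resnik similarity between two families of classes.
// anc_a / anc_b hold, per class, the 1-based indices (into `ic`) of its
// ancestors that are present in the information-content table. Entry (i, j)
// is the maximum IC over shared ancestors, 0 when only zero-frequency
// classes are shared.
// [[Rcpp::export]]
NumericMatrix resnik_class_matrix(List anc_a, List anc_b, NumericVector ic) {
  int na = anc_a.size(), nb = anc_b.size(), n = ic.size();
  NumericMatrix out(na, nb);
  std::vector<double> mark(n, -1.0);
  std::vector<int> stamp(n, -1);
  for (int i = 0; i < na; ++i) {
    IntegerVector ai = anc_a[i];
    for (int k = 0; k < ai.size(); ++k) {
      int c = ai[k] - 1;
      mark[c] = ic[c];
      stamp[c] = i;
    }
    for (int j = 0; j < nb; ++j) {
      IntegerVector bj = anc_b[j];
      double best = 0.0;
      for (int k = 0; k < bj.size(); ++k) {
        int c = bj[k] - 1;
        if (stamp[c] == i && mark[c] > best) best = mark[c];
      }
      out(i, j) = best;
    }
  }
  return out;
}

// Symmetric best-match-average over a precomputed class-level similarity
// matrix. gene_sets / disease_sets contain 1-based row / column indices of R
// for each entity's direct annotation classes; an empty set scores 0.
// [[Rcpp::export]]
NumericMatrix bma_from_class_matrix(List gene_sets, List disease_sets,
                                    NumericMatrix R) {
  int ng = gene_sets.size(), nd = disease_sets.size();
  NumericMatrix out(ng, nd);
  for (int g = 0; g < ng; ++g) {
    IntegerVector gi = gene_sets[g];
    if (gi.size() == 0) continue;
    for (int d = 0; d < nd; ++d) {
      IntegerVector dj = disease_sets[d];
      if (dj.size() == 0) continue;
      double row_sum = 0.0;
      std::vector<double> col_max(dj.size(), 0.0);
      for (int a = 0; a < gi.size(); ++a) {
        double row_max = 0.0;
        int ri = gi[a] - 1;
        for (int b = 0; b < dj.size(); ++b) {
          double v = R(ri, dj[b] - 1);
          if (v > row_max) row_max = v;
          if (v > col_max[b]) col_max[b] = v;
        }
        row_sum += row_max;
      }
      double col_sum = 0.0;
      for (int b = 0; b < dj.size(); ++b) col_sum += col_max[b];
      out(g, d) = 0.5 * (row_sum / gi.size() + col_sum / dj.size());
    }
  }
  return out;
}

// Uniform random walks over a CSR adjacency structure. offsets is 0-based of
// length n_nodes+1; nbr holds 0-based neighbor node indices and lab 0-based
// edge-label token offsets. Emitted sentences are 1-based token ids where
// node i has token id i+1 and label l has token id n_nodes+l+1. A walk
// truncates at a sink node.
// [[Rcpp::export]]
List random_walks_cpp(IntegerVector offsets, IntegerVector nbr,
                      IntegerVector lab, int n_nodes, int num_walks,
                      int walk_length, double seed) {
  XRng rng(seed);
  List out(n_nodes * num_walks);
  int pos = 0;
  std::vector<int> buf;
  for (int v = 0; v < n_nodes; ++v) {
    for (int w = 0; w < num_walks; ++w) {
      buf.clear();
      buf.push_back(v + 1);
      int cur = v;
      for (int step = 0; step < walk_length; ++step) {
        int deg = offsets[cur + 1] - offsets[cur];
        if (deg == 0) break;
        int k = offsets[cur] + rng.below(deg);
        buf.push_back(n_nodes + lab[k] + 1);
        buf.push_back(nbr[k] + 1);
        cur = nbr[k];
      }
      out[pos++] = IntegerVector(buf.begin(), buf.end());
    }
  }
  return out;
}

static inline double sigmoid_(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling (word2vec-style), single-threaded and
// deterministic for a given seed. sentences hold 0-based vocabulary indices;
// freq the vocabulary counts used to build the 0.75-power unigram table.
// Learning rate decays linearly to 1e-4 * alpha over the training stream.
// Returns the input-vector matrix (vocab x dim).
// [[Rcpp::export]]
NumericMatrix sgns_train_cpp(List sentences, int vocab, NumericVector freq,
                             int dim, int window, int negatives, int epochs,
                             double alpha, double seed) {
  XRng rng(seed);
  std::vector<double> syn0((size_t)vocab * dim), syn1((size_t)vocab * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  const int table_size = 100000;
  std::vector<int> table(table_size);
  {
    double z = 0.0;
    std::vector<double> pw(vocab);
    for (int i = 0; i < vocab; ++i) { pw[i] = std::pow(freq[i], 0.75); z += pw[i]; }
    int i = 0;
    double cum = pw[0] / z;
    for (int t = 0; t < table_size; ++t) {
      table[t] = i;
      if ((t + 1.0) / table_size > cum && i < vocab - 1) {
        ++i;
        cum += pw[i] / z;
      }
    }
  }

  double total_words = 0.0;
  for (int s = 0; s < sentences.size(); ++s)
    total_words += ((IntegerVector)sentences[s]).size();
  total_words *= epochs;
  double trained = 0.0;
  std::vector<double> neu1e(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < sentences.size(); ++s) {
      IntegerVector sent = sentences[s];
      int len = sent.size();
      for (int pos = 0; pos < len; ++pos) {
        double lr = alpha * (1.0 - trained / (total_words + 1.0));
        if (lr < alpha * 1e-4) lr = alpha * 1e-4;
        trained += 1.0;
        int b = rng.below(window);
        for (int a = b; a < window * 2 + 1 - b; ++a) {
          if (a == window) continue;
          int c = pos - window + a;
          if (c < 0 || c >= len) continue;
          int ctx = sent[c];
          double *v0 = &syn0[(size_t)ctx * dim];
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int d = 0; d <= negatives; ++d) {
            int target;
            double label;
            if (d == 0) {
              target = sent[pos];
              label = 1.0;
            } else {
              target = table[rng.below(table_size)];
              if (target == sent[pos]) continue;
              label = 0.0;
            }
            double *v1 = &syn1[(size_t)target * dim];
            double f = 0.0;
            for (int k = 0; k < dim; ++k) f += v0[k] * v1[k];
            double g = (label - sigmoid_(f)) * lr;
            for (int k = 0; k < dim; ++k) neu1e[k] += g * v1[k];
            for (int k = 0; k < dim; ++k) v1[k] += g * v0[k];
          }
          for (int k = 0; k < dim; ++k) v0[k] += neu1e[k];
        }
      }
    }
  }

  NumericMatrix out(vocab, dim);
  for (int i = 0; i < vocab; ++i)
    for (int k = 0; k < dim; ++k) out(i, k) = syn0[(size_t)i * dim + k];
  return out;
}
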