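#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// All sampling goes through unif_rand() so that set.seed() on the R side
// makes walks and training fully reproducible (single-threaded by design).

static inline int sampleWeighted(const std::vector<double>& w, double total) {
  double r = unif_rand() * total;
  double acc = 0.0;
  for (size_t i = 0; i < w.size(); ++i) {
    acc += w[i];
    if (r <= acc) return (int)i;
  }
  return (int)w.size() - 1;
}

// Second-order biased random walks. adj/wts are 0-based adjacency lists
// (neighbours sorted ascending, weights aligned). Bias on the step from
// `prev` over current node's neighbour x with edge weight w:
//   w / p  if x == prev (return)
//   w      if x is a neighbour of prev (common neighbour)
//   w / q  otherwise (outward)
// [[Rcpp::export]]
List cpp_walks(List adj, List wts, double p, double q,
               int walk_length, int walks_per_node) {
  int n = adj.size();
  std::vector<std::vector<int> > nbr(n);
  std::vector<std::vector<double> > wt(n);
  for (int i = 0; i < n; ++i) {
    nbr[i] = as<std::vector<int> >(adj[i]);
    wt[i] = as<std::vector<double> >(wts[i]);
  }
  std::vector<std::vector<int> > walks;
  walks.reserve((size_t)n * walks_per_node);
  std::vector<double> bias;
  for (int r = 0; r < walks_per_node; ++r) {
    for (int s = 0; s < n; ++s) {
      std::vector<int> walk;
      walk.reserve(walk_length);
      walk.push_back(s);
      if (!nbr[s].empty()) {
        // first step: weight-proportional (no previous node yet)
        double tot = 0.0;
        for (double w : wt[s]) tot += w;
        int cur = nbr[s][sampleWeighted(wt[s], tot)];
        walk.push_back(cur);
        int prev = s;
        while ((int)walk.size() < walk_length && !nbr[cur].empty()) {
          const std::vector<int>& cn = nbr[cur];
          const std::vector<double>& cw = wt[cur];
          bias.assign(cn.size(), 0.0);
          double tot2 = 0.0;
          for (size_t k = 0; k < cn.size(); ++k) {
            double b;
            if (cn[k] == prev) {
              b = cw[k] / p;
            } else if (std::binary_search(nbr[prev].begin(),
                                          nbr[prev].end(), cn[k])) {
              b = cw[k];
            } else {
              b = cw[k] / q;
            }
            bias[k] = b;
            tot2 += b;
          }
          int nxt = cn[sampleWeighted(bias, tot2)];
          walk.push_back(nxt);
          prev = cur;
          cur = nxt;
        }
      }
      walks.push_back(walk);
    }
  }
  List out(walks.size());
  for (size_t i = 0; i < walks.size(); ++i) {
    IntegerVector v(walks[i].size());
    for (size_t j = 0; j < walks[i].size(); ++j) v[j] = walks[i][j] + 1;
    out[i] = v;
  }
  return out;
}

static inline double sigmoidClip(double x) {
  if (x > 6.0) return 1.0;
  if (x < -6.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling over a walk corpus. walks are 1-based
// integer vectors; returns the vocab x dim input-embedding matrix. Negative
// targets are drawn from the unigram distribution raised to 3/4, the
// standard smoothing. Learning rate decays linearly over processed tokens.
// [[Rcpp::export]]
NumericMatrix cpp_sgns(List walks, int vocab, int dim, int window,
                       int epochs, int negative, double alpha) {
  std::vector<std::vector<int> > corpus(walks.size());
  std::vector<double> freq(vocab, 0.0);
  long long total_tokens = 0;
  for (int i = 0; i < walks.size(); ++i) {
    IntegerVector v = walks[i];
    corpus[i].resize(v.size());
    for (int j = 0; j < v.size(); ++j) {
      corpus[i][j] = v[j] - 1;
      freq[corpus[i][j]] += 1.0;
    }
    total_tokens += v.size();
  }
  // unigram^0.75 sampling table
  const int TABLE = 1 << 20;
  std::vector<int> table(TABLE);
  double z = 0.0;
  for (int i = 0; i < vocab; ++i) z += std::pow(freq[i], 0.75);
  int cell = 0;
  double cum = std::pow(freq[0], 0.75) / z;
  for (int i = 0; i < TABLE; ++i) {
    table[i] = cell;
    if ((double)i / TABLE > cum && cell < vocab - 1) {
      ++cell;
      cum += std::pow(freq[cell], 0.75) / z;
    }
  }
  std::vector<double> syn0((size_t)vocab * dim);
  std::vector<double> syn1((size_t)vocab * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (unif_rand() - 0.5) / dim;
  std::vector<double> grad(dim);
  const double minAlpha = alpha * 1e-4;
  long long processed = 0;
  const long long planned = total_tokens * (long long)epochs;
  for (int ep = 0; ep < epochs; ++ep) {
    for (size_t s = 0; s < corpus.size(); ++s) {
      const std::vector<int>& sen = corpus[s];
      int len = (int)sen.size();
      for (int pos = 0; pos < len; ++pos) {
        ++processed;
        double lr = alpha * (1.0 - (double)processed / (planned + 1));
        if (lr < minAlpha) lr = minAlpha;
        int b = (int)(unif_rand() * window);  // dynamic window shrink
        for (int off = b - window; off <= window - b; ++off) {
          if (off == 0) continue;
          int cpos = pos + off;
          if (cpos < 0 || cpos >= len) continue;
          double* v_in = &syn0[(size_t)sen[cpos] * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int d = 0; d < negative + 1; ++d) {
            int target;
            double label;
            if (d == 0) {
              target = sen[pos];
              label = 1.0;
            } else {
              target = table[(int)(unif_rand() * TABLE)];
              if (target == sen[pos]) continue;
              label = 0.0;
            }
            double* v_out = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int k = 0; k < dim; ++k) dot += v_in[k] * v_out[k];
            double g = (label - sigmoidClip(dot)) * lr;
            for (int k = 0; k < dim; ++k) {
              grad[k] += g * v_out[k];
              v_out[k] += g * v_in[k];
            }
          }
          for (int k = 0; k < dim; ++k) v_in[k] += grad[k];
        }
      }
    }
  }
  NumericMatrix out(vocab, dim);
  for (int i = 0; i < vocab; ++i)
    for (int k = 0; k < dim; ++k)
      out(i, k) = syn0[(size_t)i * dim + k];
  return out;
}
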