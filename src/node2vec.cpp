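// Biased second-order random walks and skip-gram-with-negative-sampling
// embedding training. Both use a private xorshift RNG so results are fully
// reproducible from the integer seed, independent of R's RNG state and of
// thread count (everything is single-threaded).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    // splitmix64-style scrambling of a xorshift64 state
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  double unif() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
};

// weighted draw from unnormalized weights
int draw(const std::vector<double>& w, double total, XorShift& rng) {
  double u = rng.unif() * total;
  double acc = 0.0;
  for (size_t i = 0; i < w.size(); ++i) {
    acc += w[i];
    if (u <= acc) return static_cast<int>(i);
  }
  return static_cast<int>(w.size()) - 1;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_biased_walks")]]
List cpp_biased_walks(NumericMatrix adj, int walks_per_node, int walk_length,
                      double p, double q, int seed) {
  const int n = adj.nrow();
  // adjacency lists
  std::vector<std::vector<int> > nbr(n);
  std::vector<std::vector<double> > wgt(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (adj(i, j) > 0.0) {
        nbr[i].push_back(j);
        wgt[i].push_back(adj(i, j));
      }
  XorShift rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);
  List out(n * walks_per_node);
  int idx = 0;
  std::vector<double> w;
  for (int r = 0; r < walks_per_node; ++r) {
    for (int v0 = 0; v0 < n; ++v0) {
      std::vector<int> walk;
      walk.reserve(walk_length);
      walk.push_back(v0);
      int prev = -1;
      while (static_cast<int>(walk.size()) < walk_length) {
        int cur = walk.back();
        const std::vector<int>& nb = nbr[cur];
        if (nb.empty()) break;  // isolated node: terminate immediately
        w.assign(nb.size(), 0.0);
        double total = 0.0;
        for (size_t k = 0; k < nb.size(); ++k) {
          double base = wgt[cur][k];
          double bias = 1.0;
          if (prev >= 0) {
            if (nb[k] == prev) bias = 1.0 / p;          // return step
            else if (adj(nb[k], prev) > 0.0) bias = 1.0; // distance 1
            else bias = 1.0 / q;                         // distance 2
          }
          w[k] = base * bias;
          total += w[k];
        }
        int nxt = nb[draw(w, total, rng)];
        prev = cur;
        walk.push_back(nxt);
      }
      IntegerVector iv(walk.size());
      for (size_t k = 0; k < walk.size(); ++k) iv[k] = walk[k] + 1;  // 1-based
      out[idx++] = iv;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_sgns_train")]]
NumericMatrix cpp_sgns_train(List corpus, int n_nodes, int dim, int window,
                             int epochs, int negative, double alpha,
                             int seed) {
  // token counts for the unigram^0.75 negative-sampling table
  std::vector<double> cnt(n_nodes, 0.0);
  long long total_tokens = 0;
  for (int s = 0; s < corpus.size(); ++s) {
    IntegerVector seq = corpus[s];
    for (int t = 0; t < seq.size(); ++t) {
      cnt[seq[t] - 1] += 1.0;
      ++total_tokens;
    }
  }
  const int table_size = 1 << 17;
  std::vector<int> table(table_size);
  {
    double z = 0.0;
    for (int i = 0; i < n_nodes; ++i) z += std::pow(cnt[i], 0.75);
    double acc = std::pow(cnt[0], 0.75) / z;
    int i = 0;
    for (int k = 0; k < table_size; ++k) {
      table[k] = i;
      if (static_cast<double>(k + 1) / table_size > acc && i < n_nodes - 1) {
        ++i;
        acc += std::pow(cnt[i], 0.75) / z;
      }
    }
  }
  XorShift rng(static_cast<uint64_t>(seed) * 6364136223846793005ULL + 7ULL);
  // init: input vectors uniform in [-0.5, 0.5]/dim, output vectors zero
  std::vector<double> win(static_cast<size_t>(n_nodes) * dim);
  std::vector<double> wout(static_cast<size_t>(n_nodes) * dim, 0.0);
  for (size_t i = 0; i < win.size(); ++i)
    win[i] = (rng.unif() - 0.5) / dim;
  const double alpha_min = alpha * 0.0001;
  long long processed = 0;
  const long long planned = static_cast<long long>(epochs) * total_tokens;
  std::vector<double> grad(dim);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < corpus.size(); ++s) {
      IntegerVector seq = corpus[s];
      const int len = seq.size();
      for (int t = 0; t < len; ++t) {
        double lr = alpha * (1.0 - static_cast<double>(processed) / planned);
        if (lr < alpha_min) lr = alpha_min;
        ++processed;
        // dynamic window as in word2vec
        int b = static_cast<int>(rng.next() % static_cast<uint64_t>(window));
        int center = seq[t] - 1;
        for (int off = b - window; off <= window - b; ++off) {
          if (off == 0) continue;
          int tc = t + off;
          if (tc < 0 || tc >= len) continue;
          int context = seq[tc] - 1;
          double* vin = &win[static_cast<size_t>(context) * dim];
          for (int d = 0; d < dim; ++d) grad[d] = 0.0;
          for (int neg = 0; neg <= negative; ++neg) {
            int target;
            double label;
            if (neg == 0) { target = center; label = 1.0; }
            else {
              target = table[rng.next() % table_size];
              if (target == center) continue;
              label = 0.0;
            }
            double* vout = &wout[static_cast<size_t>(target) * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += vin[d] * vout[d];
            double pred = 1.0 / (1.0 + std::exp(-dot));
            double g = (label - pred) * lr;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * vout[d];
              vout[d] += g * vin[d];
            }
          }
          for (int d = 0; d < dim; ++d) vin[d] += grad[d];
        }
      }
    }
  }
  NumericMatrix out(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int d = 0; d < dim; ++d)
      out(i, d) = win[static_cast<size_t>(i) * dim + d];
  return out;
}
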