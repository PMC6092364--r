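#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Greedy multi-level optimisation of a generalised quality function
//   Q(partition) = sum_{i,j in same community} F[i, j]
// for a dense symmetric matrix F that may contain negative entries (the
// null-model term is already inside F, unlike plain modularity), as used
// by Markov Stability. The node sweep order is shuffled with a local
// xorshift64 generator so runs are deterministic given `seed` and
// independent of R's RNG state.

namespace {

struct XorShift64 {
  uint64_t s;
  explicit XorShift64(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

// one node-sweep phase on matrix F; comm holds labels in 0..N-1
bool one_level(const std::vector<double>& F, int N, std::vector<int>& comm,
               XorShift64& rng, double tol) {
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  std::vector<double> wlink(N, 0.0);
  std::vector<int> touched;
  touched.reserve(N);

  bool any_improvement = false;
  bool improved = true;
  int sweep = 0;
  while (improved && sweep < 256) {
    improved = false;
    ++sweep;
    for (int i = N - 1; i > 0; --i) {
      int j = rng.below(i + 1);
      std::swap(order[i], order[j]);
    }
    for (int oi = 0; oi < N; ++oi) {
      int i = order[oi];
      int a = comm[i];
      touched.clear();
      const double* col = &F[static_cast<size_t>(i) * N]; // symmetric: col == row
      for (int j = 0; j < N; ++j) {
        if (j == i) continue;
        double f = col[j];
        if (f == 0.0) continue;
        int c = comm[j];
        if (wlink[c] == 0.0) touched.push_back(c);
        wlink[c] += f;
      }
      if (wlink[a] == 0.0) touched.push_back(a); // ensure base community known
      double base = wlink[a];
      int best = a;
      double best_gain = tol; // strictly improving moves only
      for (size_t k = 0; k < touched.size(); ++k) {
        int c = touched[k];
        if (c == a) continue;
        double gain = 2.0 * (wlink[c] - base);
        if (gain > best_gain || (gain == best_gain && best != a && c < best)) {
          best_gain = gain;
          best = c;
        }
      }
      for (size_t k = 0; k < touched.size(); ++k) wlink[touched[k]] = 0.0;
      if (best != a) {
        comm[i] = best;
        improved = true;
        any_improvement = true;
      }
    }
  }
  return any_improvement;
}

void compact(std::vector<int>& comm, int N, int& C) {
  std::vector<int> remap(N, -1);
  C = 0;
  for (int i = 0; i < N; ++i) {
    if (remap[comm[i]] < 0) remap[comm[i]] = C++;
    comm[i] = remap[comm[i]];
  }
}

} // namespace

// [[Rcpp::export(name = ".louvain_cpp")]]
IntegerVector louvain_cpp(NumericMatrix Fsym, double seed) {
  int N = Fsym.nrow();
  if (N != Fsym.ncol()) stop("matrix must be square");
  if (N == 0) return IntegerVector(0);

  double scale = 0.0;
  for (int k = 0; k < N * N; ++k) scale = std::max(scale, std::fabs(Fsym[k]));
  if (scale == 0.0) {              // degenerate objective: everything ties
    IntegerVector ones(N, 1);
    return ones;
  }
  // relative gain threshold: the objective decays like exp(-(1-lambda) t),
  // so an absolute cutoff would freeze the optimiser at large Markov times
  double tol = 1e-12 * scale;

  XorShift64 rng(static_cast<uint64_t>(seed) + 0x5DEECE66DULL);

  std::vector<double> F(Fsym.begin(), Fsym.end());
  int n = N;
  std::vector<int> node2comm(N);
  for (int i = 0; i < N; ++i) node2comm[i] = i;

  while (true) {
    std::vector<int> comm(n);
    for (int i = 0; i < n; ++i) comm[i] = i;
    bool improved = one_level(F, n, comm, rng, tol);
    int C;
    compact(comm, n, C);
    // fold level assignment into the node-level partition
    for (int i = 0; i < N; ++i) node2comm[i] = comm[node2comm[i]];
    if (!improved || C == n) break;
    // aggregate F into the C x C community matrix
    std::vector<double> Fagg(static_cast<size_t>(C) * C, 0.0);
    for (int j = 0; j < n; ++j) {
      int cj = comm[j];
      const double* col = &F[static_cast<size_t>(j) * n];
      for (int i = 0; i < n; ++i) {
        Fagg[static_cast<size_t>(cj) * C + comm[i]] += col[i];
      }
    }
    F.swap(Fagg);
    n = C;
  }

  IntegerVector out(N);
  for (int i = 0; i < N; ++i) out[i] = node2comm[i] + 1; // 1-based for R
  return out;
}
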