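#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Counter-seeded RNG (splitmix64 seeding an xorshift128+ stream) so that each
// locus gets its own reproducible substream, independent of how many loci are
// simulated in the batch.
namespace {

struct LocusRng {
  uint64_t s0, s1;
  explicit LocusRng(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 2; ++i) {
      z += 0x9E3779B97F4A7C15ULL;
      uint64_t r = z;
      r = (r ^ (r >> 30)) * 0xBF58476D1CE4E5B9ULL;
      r = (r ^ (r >> 27)) * 0x94D049BB133111EBULL;
      r ^= (r >> 31);
      if (i == 0) s0 = r; else s1 = r;
    }
    if (s0 == 0 && s1 == 0) s0 = 0x1234567887654321ULL;
  }
  uint64_t nextU64() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  double unif() { return (nextU64() >> 11) * (1.0 / 9007199254740992.0); }
  double exp1() {
    double u = unif();
    while (u <= 0.0) u = unif();
    return -std::log(u);
  }
  int below(int n) {
    // small n: rejection-free scaled draw is fine here
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

inline uint64_t locusSeed(uint64_t seed, uint64_t locus) {
  uint64_t z = seed * 0x9E3779B97F4A7C15ULL + locus * 0xBF58476D1CE4E5B9ULL + 0x94D049BB133111EBULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Merger {
  int a, b;
  double t;
};

// Coalesce lineages in `S` over the time window [t0, t1] (t1 = +Inf for the
// root edge, where coalescence continues until one lineage remains).
void coalesceEdge(std::vector<int>& S, double t0, double t1, LocusRng& rng,
                  std::vector<Merger>& mergers, int& nextId) {
  double t = t0;
  while (S.size() >= 2) {
    double k = (double)S.size();
    double rate = k * (k - 1.0) / 2.0;
    double dt = rng.exp1() / rate;
    if (t + dt > t1) return;
    t += dt;
    int i = rng.below((int)S.size());
    int j = rng.below((int)S.size() - 1);
    if (j >= i) ++j;
    Merger m;
    m.a = S[i]; m.b = S[j]; m.t = t;
    mergers.push_back(m);
    int keep = nextId++;
    if (i > j) std::swap(i, j);
    S[i] = keep;
    S[j] = S.back();
    S.pop_back();
  }
}

} // namespace

// Simulate gene trees under the multispecies coalescent on a (time-consistent)
// species network.  Nodes are 1-based ids; `procOrder` lists all node ids in
// ascending time with the root last.  `parent1`/`parent2` give each node's
// parent node id (0 = none); `probTo1` is the probability that a lineage at a
// hybrid node follows parent1 (1.0 at tree nodes).  `tipSets` holds, per
// locus, the network tip ids sampled (lineage i of that locus corresponds to
// element i of the tip set).  Returns, per locus, the merger record
// (child ids a, b and coalescence time t; new internal lineages are numbered
// k+1, k+2, ... in merge order) plus per-hybrid lineage routing counts.
// [[Rcpp::export(name = ".simCoalescentBatch")]]
List simCoalescentBatch(IntegerVector procOrder,
                        NumericVector nodeTime,
                        IntegerVector parent1,
                        IntegerVector parent2,
                        NumericVector probTo1,
                        IntegerVector hybridNodes,
                        List tipSets,
                        double seed,
                        double locusOffset) {
  const int nNodes = nodeTime.size();
  const int nLoci = tipSets.size();
  const int nHyb = hybridNodes.size();
  std::vector<int> hybIndex(nNodes + 1, -1);
  for (int h = 0; h < nHyb; ++h) hybIndex[hybridNodes[h]] = h;

  List out(nLoci);
  IntegerMatrix hybArrive(nLoci, nHyb);
  IntegerMatrix hybTo1(nLoci, nHyb);

  for (int loc = 0; loc < nLoci; ++loc) {
    IntegerVector tips = tipSets[loc];
    const int k = tips.size();
    LocusRng rng(locusSeed((uint64_t)(int64_t)seed, (uint64_t)(int64_t)(locusOffset + loc + 1)));

    std::vector<std::vector<int> > arriving(nNodes + 1);
    for (int i = 0; i < k; ++i) arriving[tips[i]].push_back(i + 1);

    std::vector<Merger> mergers;
    mergers.reserve(k > 0 ? k - 1 : 0);
    int nextId = k + 1;

    for (int oi = 0; oi < procOrder.size(); ++oi) {
      int v = procOrder[oi];
      std::vector<int>& L = arriving[v];
      bool isRoot = (parent1[v - 1] == 0);
      if (isRoot) {
        coalesceEdge(L, nodeTime[v - 1], R_PosInf, rng, mergers, nextId);
        break; // root is last in procOrder
      }
      if (L.empty()) continue;
      int p1 = parent1[v - 1], p2 = parent2[v - 1];
      if (p2 == 0) {
        // tree node: all lineages continue into the single parent edge
        std::vector<int> S;
        S.swap(L);
        coalesceEdge(S, nodeTime[v - 1], nodeTime[p1 - 1], rng, mergers, nextId);
        for (size_t i = 0; i < S.size(); ++i) arriving[p1].push_back(S[i]);
      } else {
        // hybrid node: each lineage independently picks a parent edge
        double g = probTo1[v - 1];
        std::vector<int> S1, S2;
        for (size_t i = 0; i < L.size(); ++i) {
          bool to1;
          if (g >= 1.0) to1 = true;
          else if (g <= 0.0) to1 = false;
          else to1 = (rng.unif() < g);
          if (to1) S1.push_back(L[i]); else S2.push_back(L[i]);
        }
        int hi = hybIndex[v];
        if (hi >= 0) {
          hybArrive(loc, hi) = (int)L.size();
          hybTo1(loc, hi) = (int)S1.size();
        }
        L.clear();
        coalesceEdge(S1, nodeTime[v - 1], nodeTime[p1 - 1], rng, mergers, nextId);
        for (size_t i = 0; i < S1.size(); ++i) arriving[p1].push_back(S1[i]);
        coalesceEdge(S2, nodeTime[v - 1], nodeTime[p2 - 1], rng, mergers, nextId);
        for (size_t i = 0; i < S2.size(); ++i) arriving[p2].push_back(S2[i]);
      }
    }

    const int nm = (int)mergers.size();
    IntegerVector a(nm), b(nm);
    NumericVector t(nm);
    for (int m = 0; m < nm; ++m) {
      a[m] = mergers[m].a;
      b[m] = mergers[m].b;
      t[m] = mergers[m].t;
    }
    out[loc] = List::create(Named("a") = a, Named("b") = b, Named("t") = t);
  }

  return List::create(Named("loci") = out,
                      Named("hybridArrivals") = hybArrive,
                      Named("hybridToFirst") = hybTo1);
}

// Deterministic per-locus uniform draws from the same counter-seeded stream
// family (used for mutation placement, SNP positions and genotype masking so
// locus i is reproducible independently of n_loci).
// [[Rcpp::export(name = ".locusUniforms")]]
NumericVector locusUniforms(double seed, double locus, double salt, int n) {
  LocusRng rng(locusSeed((uint64_t)(int64_t)seed ^ ((uint64_t)(int64_t)salt << 32),
                         (uint64_t)(int64_t)locus));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.unif();
  return out;
}
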