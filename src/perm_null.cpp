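#include <Rcpp.h>
using namespace Rcpp;

// Permutation null for the windowed minimum-divergence scan.
//
// ind_t: k x n integer matrix of per-site difference indicators
//        (rows = reference strains, cols = valid sites).
// g:     1-based window index per valid site.
// B:     number of permutations.
// n_neg: the first n_neg rows of ind_t belong to the negative-sign
//        population, the rest to the positive-sign one.
//
// Each permutation shuffles the site -> window assignment (preserving
// every window's valid-site count), accumulates per-window per-strain
// difference counts, and records the minimum count on each side.
// The shuffle uses a xoshiro256++ stream seeded from R's RNG, so results
// are reproducible under set.seed() without paying for one R RNG call
// per site per permutation.

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // unbiased bounded draw (Lemire with rejection)
  inline uint64_t bounded(uint64_t range) {
    uint64_t x = next();
    __uint128_t m = (__uint128_t)x * range;
    uint64_t l = (uint64_t)m;
    if (l < range) {
      uint64_t t = (-range) % range;
      while (l < t) {
        x = next();
        m = (__uint128_t)x * range;
        l = (uint64_t)m;
      }
    }
    return (uint64_t)(m >> 64);
  }
};

// [[Rcpp::export]]
List perm_null_min_counts(IntegerMatrix ind_t, IntegerVector g,
                          int n_windows, int B, int n_neg) {
  const int k = ind_t.nrow();
  const R_xlen_t n = ind_t.ncol();
  if (g.size() != n) stop("g length mismatch");
  IntegerMatrix min_neg(B, n_windows), min_pos(B, n_windows);
  std::vector<int> gp(g.begin(), g.end());
  std::vector<int> acc((size_t)k * n_windows);
  uint64_t seed;
  {
    RNGScope scope;
    seed = (uint64_t)(unif_rand() * 4294967296.0) << 32;
    seed |= (uint64_t)(unif_rand() * 4294967296.0);
  }
  Xoshiro256pp rng(seed);
  for (int b = 0; b < B; ++b) {
    // Fisher-Yates shuffle of the window labels
    for (R_xlen_t i = n - 1; i > 0; --i) {
      R_xlen_t j = (R_xlen_t)rng.bounded((uint64_t)i + 1);
      std::swap(gp[i], gp[j]);
    }
    std::fill(acc.begin(), acc.end(), 0);
    const int *ind = ind_t.begin();
    for (R_xlen_t s = 0; s < n; ++s) {
      int *aw = &acc[(size_t)(gp[s] - 1) * k];
      const int *col = ind + (size_t)s * k;
      for (int j = 0; j < k; ++j) aw[j] += col[j];
    }
    for (int w = 0; w < n_windows; ++w) {
      const int *aw = &acc[(size_t)w * k];
      int mn = INT_MAX, mp = INT_MAX;
      for (int j = 0; j < n_neg; ++j) mn = std::min(mn, aw[j]);
      for (int j = n_neg; j < k; ++j) mp = std::min(mp, aw[j]);
      min_neg(b, w) = mn;
      min_pos(b, w) = mp;
    }
  }
  return List::create(_["min_neg"] = min_neg, _["min_pos"] = min_pos);
}
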