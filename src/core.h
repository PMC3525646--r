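#ifndef NETMOTIF_CORE_H
#define NETMOTIF_CORE_H

#include <Rcpp.h>
#include <cstdint>
#include <functional>
#include <vector>
#include <array>
#include <algorithm>
#include <unordered_set>
#include <unordered_map>

// A k-node digraph is encoded as its adjacency matrix read row-major as a
// binary number, most significant bit first: entry (i, j) (0-based) has
// weight 2^(k*k - 1 - (k*i + j)).  Diagonal bits are always zero (loop-free).
// k <= 8 fits in a uint64_t (8*8 = 64 bits).

inline int bitpos(int k, int i, int j) { return k * k - 1 - (k * i + j); }

inline bool get_bit(uint64_t id, int k, int i, int j) {
  return (id >> bitpos(k, i, j)) & 1ULL;
}

inline uint64_t set_bit(uint64_t id, int k, int i, int j) {
  return id | (1ULL << bitpos(k, i, j));
}

// Relabel: vertex i of the result is vertex perm[i] of the input.
inline uint64_t permute_id(uint64_t id, int k, const int* perm) {
  uint64_t out = 0;
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j) {
      if (i == j) continue;
      if (get_bit(id, k, perm[i], perm[j])) out = set_bit(out, k, i, j);
    }
  return out;
}

// Exchange two vertex labels (transposition a <-> b).
inline uint64_t swap_labels(uint64_t id, int k, int a, int b) {
  int perm[8];
  for (int i = 0; i < k; ++i) perm[i] = i;
  perm[a] = b; perm[b] = a;
  return permute_id(id, k, perm);
}

// Minimum graphID over all k! relabelings.
inline uint64_t canonical_min(uint64_t id, int k) {
  int p[8];
  for (int i = 0; i < k; ++i) p[i] = i;
  uint64_t best = id;
  while (std::next_permutation(p, p + k)) {
    uint64_t v = permute_id(id, k, p);
    if (v < best) best = v;
  }
  return best;
}

// Pack the k*(k-1) off-diagonal bits (row-major, first off-diagonal entry
// most significant) into a dense table index.
inline uint32_t pack_id(uint64_t id, int k) {
  uint32_t p = 0;
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j) {
      if (i == j) continue;
      p = (p << 1) | (uint32_t)get_bit(id, k, i, j);
    }
  return p;
}

inline uint64_t unpack_id(uint32_t p, int k) {
  uint64_t id = 0;
  int nb = k * (k - 1), t = 0;
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j) {
      if (i == j) continue;
      if ((p >> (nb - 1 - t)) & 1U) id = set_bit(id, k, i, j);
      ++t;
    }
  return id;
}

// Weak connectivity of an encoded k-node graph (union-find).
inline bool id_connected(uint64_t id, int k) {
  int parent[8];
  for (int i = 0; i < k; ++i) parent[i] = i;
  // find with path halving
  auto find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  int comps = k;
  for (int i = 0; i < k; ++i)
    for (int j = i + 1; j < k; ++j) {
      if (get_bit(id, k, i, j) || get_bit(id, k, j, i)) {
        int a = find(i), b = find(j);
        if (a != b) { parent[a] = b; --comps; }
      }
    }
  return comps == 1;
}

// Deterministic, platform-independent RNG (splitmix64); used for everything
// random on the C++ side so that results depend only on the supplied seed.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) { next(); next(); }
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform on 0..n-1 (rejection-free; bias ~2^-58 for the small n used here)
  uint64_t below(uint64_t n) { return next() % n; }
  template <typename T>
  void shuffle(std::vector<T>& v) {
    for (size_t i = v.size(); i > 1; --i) {
      size_t j = (size_t)below(i);
      std::swap(v[i - 1], v[j]);
    }
  }
};

// Derive an independent stream seed from (master seed, stream index).
inline uint64_t stream_seed(uint64_t seed, uint64_t index) {
  Rng r(seed * 0x9E3779B97F4A7C15ULL + index * 0xD1B54A32D192ED03ULL + 0x632BE59BD9B4E019ULL);
  return r.next();
}

// Backtracking digraph isomorphism for n <= 8, with (out, in, reciprocal)
// degree-triple pruning before the permutation search.
bool iso_ids(uint64_t a, uint64_t b, int n);

#endif
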