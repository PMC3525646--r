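#include "core.h"
using namespace Rcpp;

uint64_t id_from_double(double id, int k);
uint64_t id_from_arcs(const IntegerMatrix& arcs, int k);
IntegerMatrix arcs_from_id(uint64_t id, int k);

// --- Kavosh-style rooted enumeration --------------------------------------
// For each root (ascending label), enumerate compositions of k-1 over BFS
// levels of the root's neighborhood, excluding retired roots.  All candidate
// children of a level are marked visited before subsets are chosen, so each
// connected vertex subset is produced exactly once (rooted at its minimum
// admissible vertex, with its unique BFS layering).

namespace {

struct Kavosh {
  int n, k;
  std::vector<std::vector<int>> adj;  // undirected, deduplicated, sorted
  std::vector<char> visited, banned;
  std::vector<int> selection;
  std::function<void(const std::vector<int>&)> emit;

  Kavosh(int n_, const IntegerMatrix& arcs, int k_) : n(n_), k(k_) {
    adj.assign(n, {});
    std::unordered_set<int64_t> seen;
    for (int r = 0; r < arcs.nrow(); ++r) {
      int u = arcs(r, 0), v = arcs(r, 1);
      int a = std::min(u, v), b = std::max(u, v);
      if (a == b) continue;
      if (seen.insert((int64_t)a * n + b).second) {
        adj[a].push_back(b);
        adj[b].push_back(a);
      }
    }
    for (auto& nb : adj) std::sort(nb.begin(), nb.end());
    visited.assign(n, 0);
    banned.assign(n, 0);
  }

  void run() {
    if (k > n) return;
    for (int root = 0; root < n; ++root) {
      visited[root] = 1;
      selection.push_back(root);
      std::vector<int> parents{root};
      extend(parents, k - 1);
      selection.pop_back();
      visited[root] = 0;
      banned[root] = 1;
    }
    std::fill(banned.begin(), banned.end(), 0);
  }

  void extend(const std::vector<int>& parents, int rem) {
    if (rem == 0) { emit(selection); return; }
    std::vector<int> children;
    for (int p : parents)
      for (int w : adj[p])
        if (!visited[w] && !banned[w]) {
          visited[w] = 1;
          children.push_back(w);
        }
    int c = (int)children.size();
    int qmax = std::min(rem, c);
    std::vector<int> idx;
    for (int q = 1; q <= qmax; ++q) {
      idx.resize(q);
      for (int i = 0; i < q; ++i) idx[i] = i;
      std::vector<int> sel(q);
      for (;;) {
        for (int i = 0; i < q; ++i) {
          sel[i] = children[idx[i]];
          selection.push_back(sel[i]);
        }
        extend(sel, rem - q);
        for (int i = 0; i < q; ++i) selection.pop_back();
        int t = q - 1;
        while (t >= 0 && idx[t] == c - q + t) --t;
        if (t < 0) break;
        ++idx[t];
        for (int s = t + 1; s < q; ++s) idx[s] = idx[s - 1] + 1;
      }
    }
    for (int w : children) visited[w] = 0;
  }
};

uint64_t induced_id(const std::vector<int>& S, int k,
                    const std::unordered_set<int64_t>& have, int n) {
  uint64_t id = 0;
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j) {
      if (i == j) continue;
      if (have.count((int64_t)S[i] * n + S[j])) id = set_bit(id, k, i, j);
    }
  return id;
}

std::unordered_set<int64_t> arc_set(int n, const IntegerMatrix& arcs) {
  std::unordered_set<int64_t> have;
  for (int r = 0; r < arcs.nrow(); ++r)
    have.insert((int64_t)arcs(r, 0) * n + arcs(r, 1));
  return have;
}

// 5-node cards of a 6-node graph, canonicalized through the k=5 table, sorted.
void deck_of(uint64_t id, const IntegerVector& table5, std::array<uint64_t, 6>& deck) {
  for (int d = 0; d < 6; ++d) {
    uint64_t card = 0;
    int ii = 0;
    for (int i = 0; i < 6; ++i) {
      if (i == d) continue;
      int jj = 0;
      for (int j = 0; j < 6; ++j) {
        if (j == d) continue;
        if (i != j && get_bit(id, 6, i, j)) card = set_bit(card, 5, ii, jj);
        ++jj;
      }
      ++ii;
    }
    deck[d] = (uint64_t)table5[pack_id(card, 5)];
  }
  std::sort(deck.begin(), deck.end());
}

uint64_t deck_hash(const std::array<uint64_t, 6>& deck) {
  uint64_t h = 0x243F6A8885A308D3ULL;
  for (uint64_t c : deck) {
    uint64_t z = c + 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    h ^= (z ^ (z >> 31)) + (h << 6) + (h >> 2);
  }
  return h;
}

struct Entry {
  uint64_t rep;                   // representative as first encountered
  std::array<uint64_t, 6> deck;
  double count;
};

// The subgraph list L: two-level search (hash bucket, then full deck, then
// explicit isomorphism with the stored representative).  The isomorphism
// fallback keeps classification exact even for deck-colliding class pairs.
struct SubgraphList {
  std::vector<Entry> entries;
  std::unordered_map<uint64_t, std::vector<int>> buckets;
  bool frozen = false;

  // returns entry index or -1
  int find(uint64_t id, const std::array<uint64_t, 6>& deck) {
    auto it = buckets.find(deck_hash(deck));
    if (it != buckets.end())
      for (int e : it->second)
        if (entries[e].deck == deck && iso_ids(id, entries[e].rep, 6)) return e;
    return -1;
  }

  void add(uint64_t id, const std::array<uint64_t, 6>& deck) {
    int e = find(id, deck);
    if (e >= 0) { entries[e].count += 1; return; }
    if (frozen) return;  // stage 2: classes absent from the input are ignored
    entries.push_back({id, deck, 1.0});
    buckets[deck_hash(deck)].push_back((int)entries.size() - 1);
  }
};

}  // namespace

// --- exports ---------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix enumerate_subsets_cpp(int n, IntegerMatrix arcs, int k, double max_subsets) {
  std::vector<std::vector<int>> out;
  Kavosh kav(n, arcs, k);
  kav.emit = [&](const std::vector<int>& S) {
    if ((double)out.size() >= max_subsets) stop("subset limit exceeded");
    std::vector<int> s(S);
    std::sort(s.begin(), s.end());
    out.push_back(s);
  };
  kav.run();
  IntegerMatrix m((int)out.size(), k);
  for (size_t r = 0; r < out.size(); ++r)
    for (int c = 0; c < k; ++c) m(r, c) = out[r][c];
  return m;
}

// [[Rcpp::export]]
List census_cpp(int n, IntegerMatrix arcs, int k, IntegerVector table) {
  if (k < 3 || k > 5) stop("table-based census supports k in 3..5");
  std::unordered_set<int64_t> have = arc_set(n, arcs);
  std::unordered_map<uint32_t, double> counts;
  double total = 0;
  std::vector<int> s;
  Kavosh kav(n, arcs, k);
  kav.emit = [&](const std::vector<int>& S) {
    s = S;
    std::sort(s.begin(), s.end());
    uint64_t id = induced_id(s, k, have, n);
    counts[(uint32_t)table[pack_id(id, k)]] += 1;
    total += 1;
  };
  kav.run();
  std::vector<std::pair<uint32_t, double>> v(counts.begin(), counts.end());
  std::sort(v.begin(), v.end());
  NumericVector ids((R_xlen_t)v.size()), cnt((R_xlen_t)v.size());
  for (size_t i = 0; i < v.size(); ++i) { ids[i] = v[i].first; cnt[i] = v[i].second; }
  return List::create(_["ids"] = ids, _["counts"] = cnt, _["total"] = total);
}

// Deck-based 6-node census.  With freeze_reps empty this is Stage 1 (build L
// from the input network); with freeze_reps given it is Stage 2 (count only
// classes present in the input, in the supplied order).
// [[Rcpp::export]]
List census6_cpp(int n, IntegerMatrix arcs, IntegerVector table5, NumericVector freeze_reps) {
  std::unordered_set<int64_t> have = arc_set(n, arcs);
  SubgraphList L;
  if (freeze_reps.size() > 0) {
    for (R_xlen_t i = 0; i < freeze_reps.size(); ++i) {
      uint64_t rep = id_from_double(freeze_reps[i], 6);
      std::array<uint64_t, 6> deck;
      deck_of(rep, table5, deck);
      L.entries.push_back({rep, deck, 0.0});
      L.buckets[deck_hash(deck)].push_back((int)i);
    }
    L.frozen = true;
  }
  double total = 0;
  std::vector<int> s;
  std::array<uint64_t, 6> deck;
  Kavosh kav(n, arcs, 6);
  kav.emit = [&](const std::vector<int>& S) {
    s = S;
    std::sort(s.begin(), s.end());
    uint64_t id = induced_id(s, 6, have, n);
    deck_of(id, table5, deck);
    L.add(id, deck);
    total += 1;
  };
  kav.run();
  NumericVector ids((R_xlen_t)L.entries.size()), cnt((R_xlen_t)L.entries.size());
  for (size_t i = 0; i < L.entries.size(); ++i) {
    ids[i] = (double)L.entries[i].rep;
    cnt[i] = L.entries[i].count;
  }
  return List::create(_["ids"] = ids, _["counts"] = cnt, _["total"] = total);
}

// Brute-force census oracle: all C(n, k) subsets, weak-connectivity filter,
// canonical labeling by exhaustive minimization.
// [[Rcpp::export]]
List census_bruteforce_cpp(int n, IntegerMatrix arcs, int k) {
  if (n > 15) stop("brute-force census is restricted to graphs with at most 15 nodes");
  if (k < 2 || k > 6) stop("k must be in 2..6");
  std::unordered_set<int64_t> have = arc_set(n, arcs);
  std::unordered_map<uint64_t, double> counts;
  double total = 0;
  if (k <= n) {
    std::vector<int> idx(k);
    for (int i = 0; i < k; ++i) idx[i] = i;
    for (;;) {
      uint64_t id = induced_id(idx, k, have, n);
      if (id_connected(id, k)) {
        counts[canonical_min(id, k)] += 1;
        total += 1;
      }
      int t = k - 1;
      while (t >= 0 && idx[t] == n - k + t) --t;
      if (t < 0) break;
      ++idx[t];
      for (int s2 = t + 1; s2 < k; ++s2) idx[s2] = idx[s2 - 1] + 1;
    }
  }
  std::vector<std::pair<uint64_t, double>> v(counts.begin(), counts.end());
  std::sort(v.begin(), v.end());
  NumericVector ids((R_xlen_t)v.size()), cnt((R_xlen_t)v.size());
  for (size_t i = 0; i < v.size(); ++i) { ids[i] = (double)v[i].first; cnt[i] = v[i].second; }
  return List::create(_["ids"] = ids, _["counts"] = cnt, _["total"] = total);
}

// [[Rcpp::export]]
List compute_deck_cpp(IntegerMatrix arcs6, IntegerVector table5) {
  uint64_t id = id_from_arcs(arcs6, 6);
  std::array<uint64_t, 6> deck;
  deck_of(id, table5, deck);
  NumericVector cards(6);
  for (int i = 0; i < 6; ++i) cards[i] = (double)deck[i];
  char buf[24];
  std::snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)deck_hash(deck));
  return List::create(_["cards"] = cards, _["hash"] = CharacterVector::create(buf));
}

// Search for a pair of non-isomorphic 6-node digraphs with equal decks.
// Random draws are taken among tournaments (every vertex pair joined by one
// arc), where deck-sharing non-isomorphic pairs are known to concentrate:
// tournaments are the classical counterexamples to reconstruction from
// vertex-deleted decks.  A birthday table over observed (deck, canonical id)
// reports the first collision.
// [[Rcpp::export]]
List find_deck_collision_cpp(IntegerVector table5, double seed, int max_tries) {
  Rng rng(stream_seed((uint64_t)seed, 77));
  std::unordered_map<uint64_t, std::vector<std::pair<std::array<uint64_t, 6>, uint64_t>>> seen;
  std::unordered_map<uint64_t, uint64_t> raw_by_canon;
  std::array<uint64_t, 6> deck;
  for (int t = 0; t < max_tries; ++t) {
    // random tournament: orient each of the 15 vertex pairs at random
    uint64_t id = 0;
    for (int i = 0; i < 6; ++i)
      for (int j = i + 1; j < 6; ++j)
        id = (rng.next() & 1ULL) ? set_bit(id, 6, i, j) : set_bit(id, 6, j, i);
    deck_of(id, table5, deck);
    uint64_t canon = canonical_min(id, 6);
    raw_by_canon.emplace(canon, id);
    auto& bucket = seen[deck_hash(deck)];
    for (auto& pr : bucket)
      if (pr.first == deck && pr.second != canon)
        return List::create(_["g1"] = (double)id,
                            _["g2"] = (double)raw_by_canon[pr.second],
                            _["tries"] = t + 1);
    bucket.push_back({deck, canon});
    if (t % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create();  // not found within budget
}
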