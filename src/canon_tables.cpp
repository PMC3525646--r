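#include "core.h"
using namespace Rcpp;

uint64_t id_from_double(double id, int k);

// Orbit flood-fill over the packed off-diagonal index space: starting from
// each unvisited ID, breadth-first application of the adjacent-transposition
// generators of S_k reaches the whole isomorphism orbit; every member is then
// assigned the orbit minimum.  This costs O(2^(k(k-1)) * k) relabelings in
// total instead of k! per entry.

// [[Rcpp::export]]
IntegerVector build_canon_table_cpp(int k) {
  if (k < 3 || k > 5)
    stop("canonical tables are built for k in 3..5; k = 6 uses deck-based labeling");
  int nb = k * (k - 1);
  size_t N = (size_t)1 << nb;
  IntegerVector table((R_xlen_t)N);
  std::vector<char> done(N, 0);
  std::vector<uint32_t> orbit;
  orbit.reserve(256);
  for (size_t p0 = 0; p0 < N; ++p0) {
    if (done[p0]) continue;
    orbit.clear();
    orbit.push_back((uint32_t)p0);
    done[p0] = 1;
    for (size_t qi = 0; qi < orbit.size(); ++qi) {
      uint64_t id = unpack_id(orbit[qi], k);
      for (int t = 0; t + 1 < k; ++t) {
        uint32_t sp = pack_id(swap_labels(id, k, t, t + 1), k);
        if (!done[sp]) { done[sp] = 1; orbit.push_back(sp); }
      }
    }
    uint64_t mn = UINT64_MAX;
    for (uint32_t q : orbit) mn = std::min(mn, unpack_id(q, k));
    for (uint32_t q : orbit) table[q] = (int)mn;  // k <= 5: ids < 2^25 fit int
  }
  return table;
}

// [[Rcpp::export]]
double canon_lookup_cpp(IntegerVector table, double id, int k) {
  uint64_t v = id_from_double(id, k);
  uint32_t p = pack_id(v, k);
  if ((R_xlen_t)p >= table.size()) stop("graph ID out of table range");
  return (double)table[p];
}

// Exhaustive connected-class enumeration by orbit flood-fill.
// directed: all 2^(k(k-1)) loop-free digraphs, k <= 5.
// undirected: all 2^(k(k-1)/2) graphs encoded as symmetric digraphs, k <= 6.

static uint64_t sym_id_from_mask(uint32_t mask, int k) {
  uint64_t id = 0;
  int t = 0;
  for (int i = 0; i < k; ++i)
    for (int j = i + 1; j < k; ++j, ++t)
      if ((mask >> t) & 1U) { id = set_bit(id, k, i, j); id = set_bit(id, k, j, i); }
  return id;
}

static uint32_t mask_from_sym_id(uint64_t id, int k) {
  uint32_t mask = 0;
  int t = 0;
  for (int i = 0; i < k; ++i)
    for (int j = i + 1; j < k; ++j, ++t)
      if (get_bit(id, k, i, j)) mask |= (1U << t);
  return mask;
}

// [[Rcpp::export]]
NumericVector exhaustive_connected_classes_cpp(int k, bool directed) {
  if (k < 2) stop("k must be at least 2");
  if (directed && k > 5)
    stop("exhaustive directed enumeration supports k <= 5; use growth-based enumeration");
  if (!directed && k > 6)
    stop("exhaustive undirected enumeration supports k <= 6; use growth-based enumeration");
  int nb = directed ? k * (k - 1) : k * (k - 1) / 2;
  size_t N = (size_t)1 << nb;
  std::vector<char> done(N, 0);
  std::vector<uint32_t> orbit;
  std::vector<uint64_t> classes;
  for (size_t p0 = 0; p0 < N; ++p0) {
    if (done[p0]) continue;
    orbit.clear();
    orbit.push_back((uint32_t)p0);
    done[p0] = 1;
    for (size_t qi = 0; qi < orbit.size(); ++qi) {
      uint64_t id = directed ? unpack_id(orbit[qi], k) : sym_id_from_mask(orbit[qi], k);
      for (int t = 0; t + 1 < k; ++t) {
        uint64_t sid = swap_labels(id, k, t, t + 1);
        uint32_t sp = directed ? pack_id(sid, k) : mask_from_sym_id(sid, k);
        if (!done[sp]) { done[sp] = 1; orbit.push_back(sp); }
      }
    }
    uint64_t mn = UINT64_MAX;
    for (uint32_t q : orbit)
      mn = std::min(mn, directed ? unpack_id(q, k) : sym_id_from_mask(q, k));
    if (id_connected(mn, k)) classes.push_back(mn);
  }
  std::sort(classes.begin(), classes.end());
  NumericVector out((R_xlen_t)classes.size());
  for (size_t i = 0; i < classes.size(); ++i) out[i] = (double)classes[i];
  return out;
}

// Growth-based isomorph-free enumeration: every weakly connected graph has a
// non-cut vertex (any leaf of a spanning tree), so every connected k-class
// arises by attaching one new vertex, with some nonempty neighborhood, to a
// connected (k-1)-class.  Candidates are canonicalized and deduplicated.

static std::vector<uint64_t> grow_classes(int k, bool directed) {
  if (k == 2) {
    std::vector<uint64_t> base;
    uint64_t single = set_bit(0, 2, 1, 0);          // canonical single arc
    uint64_t recip = set_bit(set_bit(0, 2, 0, 1), 2, 1, 0);
    if (directed) { base.push_back(single); base.push_back(recip); }
    else base.push_back(recip);                      // the one edge
    return base;
  }
  std::vector<uint64_t> prev = grow_classes(k - 1, directed);
  int opts = directed ? 4 : 2;  // per existing vertex: none/out/in/both or none/edge
  uint64_t ncombo = 1;
  for (int i = 0; i < k - 1; ++i) ncombo *= (uint64_t)opts;
  std::unordered_set<uint64_t> seen;
  for (uint64_t pid : prev) {
    // embed the (k-1)-node graph into vertices 0..k-2 of a k-node graph
    uint64_t embedded = 0;
    for (int i = 0; i < k - 1; ++i)
      for (int j = 0; j < k - 1; ++j)
        if (i != j && get_bit(pid, k - 1, i, j)) embedded = set_bit(embedded, k, i, j);
    for (uint64_t combo = 1; combo < ncombo; ++combo) {
      uint64_t id = embedded, c = combo;
      for (int v = 0; v < k - 1; ++v) {
        int choice = (int)(c % opts);
        c /= opts;
        if (directed) {
          if (choice & 1) id = set_bit(id, k, k - 1, v);
          if (choice & 2) id = set_bit(id, k, v, k - 1);
        } else if (choice) {
          id = set_bit(id, k, k - 1, v);
          id = set_bit(id, k, v, k - 1);
        }
      }
      seen.insert(canonical_min(id, k));
    }
    Rcpp::checkUserInterrupt();
  }
  std::vector<uint64_t> out(seen.begin(), seen.end());
  std::sort(out.begin(), out.end());
  return out;
}

// [[Rcpp::export]]
NumericVector grow_connected_classes_cpp(int k, bool directed) {
  if (k < 2) stop("k must be at least 2");
  if (directed && k > 6) stop("growth-based directed enumeration supports k <= 6");
  if (!directed && k > 7) stop("growth-based undirected enumeration supports k <= 7");
  std::vector<uint64_t> classes = grow_classes(k, directed);
  NumericVector out((R_xlen_t)classes.size());
  for (size_t i = 0; i < classes.size(); ++i) out[i] = (double)classes[i];
  return out;
}
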