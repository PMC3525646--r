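#include "core.h"
using namespace Rcpp;

// Shared helpers -----------------------------------------------------------

static void check_k_codec(int k) {
  if (k < 2 || k > 6) stop("graph IDs are defined for node counts 2..6");
}

uint64_t id_from_double(double id, int k) {
  if (!R_finite(id) || id < 0 || id != std::floor(id))
    stop("graph ID must be a non-negative integer");
  uint64_t v = (uint64_t)id;
  if (k * k < 64 && v >= (1ULL << (k * k)))
    stop("graph ID %.0f out of range for k = %d", id, k);
  for (int i = 0; i < k; ++i)
    if (get_bit(v, k, i, i))
      stop("malformed graph ID: diagonal (loop) bit set");
  return v;
}

// Build an id from a 0-based arc matrix over vertices 0..k-1.
uint64_t id_from_arcs(const IntegerMatrix& arcs, int k) {
  uint64_t id = 0;
  for (int r = 0; r < arcs.nrow(); ++r) {
    int u = arcs(r, 0), v = arcs(r, 1);
    if (u < 0 || u >= k || v < 0 || v >= k)
      stop("arc endpoint outside vertex range 0..%d", k - 1);
    if (u == v) stop("loop arc is not representable in a graph ID");
    id = set_bit(id, k, u, v);
  }
  return id;
}

IntegerMatrix arcs_from_id(uint64_t id, int k) {
  std::vector<std::pair<int, int>> arcs;
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j)
      if (i != j && get_bit(id, k, i, j)) arcs.push_back({i, j});
  IntegerMatrix out((int)arcs.size(), 2);
  for (size_t r = 0; r < arcs.size(); ++r) {
    out(r, 0) = arcs[r].first;
    out(r, 1) = arcs[r].second;
  }
  return out;
}

// Isomorphism --------------------------------------------------------------

static void degree_triples(uint64_t id, int n, std::array<int, 8>& out,
                           std::array<int, 8>& in, std::array<int, 8>& rec) {
  out.fill(0); in.fill(0); rec.fill(0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      if (get_bit(id, n, i, j)) {
        ++out[i]; ++in[j];
        if (get_bit(id, n, j, i)) ++rec[i];
      }
    }
}

static bool iso_rec(uint64_t a, uint64_t b, int n, int pos, int* mapv, bool* used,
                    const std::array<uint64_t, 8>& siga, const std::array<uint64_t, 8>& sigb) {
  if (pos == n) return true;
  for (int cand = 0; cand < n; ++cand) {
    if (used[cand] || siga[pos] != sigb[cand]) continue;
    bool ok = true;
    for (int q = 0; q < pos && ok; ++q) {
      if (get_bit(a, n, pos, q) != get_bit(b, n, cand, mapv[q])) ok = false;
      else if (get_bit(a, n, q, pos) != get_bit(b, n, mapv[q], cand)) ok = false;
    }
    if (!ok) continue;
    used[cand] = true; mapv[pos] = cand;
    if (iso_rec(a, b, n, pos + 1, mapv, used, siga, sigb)) return true;
    used[cand] = false;
  }
  return false;
}

bool iso_ids(uint64_t a, uint64_t b, int n) {
  if (a == b) return true;
  std::array<int, 8> oa, ia, ra, ob, ib, rb;
  degree_triples(a, n, oa, ia, ra);
  degree_triples(b, n, ob, ib, rb);
  // signature per vertex: (out, in, reciprocal) packed
  std::array<uint64_t, 8> siga{}, sigb{};
  std::vector<uint64_t> ms_a, ms_b;
  for (int i = 0; i < n; ++i) {
    siga[i] = ((uint64_t)oa[i] << 16) | ((uint64_t)ia[i] << 8) | (uint64_t)ra[i];
    sigb[i] = ((uint64_t)ob[i] << 16) | ((uint64_t)ib[i] << 8) | (uint64_t)rb[i];
    ms_a.push_back(siga[i]); ms_b.push_back(sigb[i]);
  }
  std::sort(ms_a.begin(), ms_a.end());
  std::sort(ms_b.begin(), ms_b.end());
  if (ms_a != ms_b) return false;
  int mapv[8]; bool used[8] = {false, false, false, false, false, false, false, false};
  return iso_rec(a, b, n, 0, mapv, used, siga, sigb);
}

// Exports ------------------------------------------------------------------

// [[Rcpp::export]]
double graph_id_cpp(IntegerMatrix arcs, int k) {
  check_k_codec(k);
  return (double)id_from_arcs(arcs, k);
}

// [[Rcpp::export]]
IntegerMatrix decode_graph_id_cpp(double id, int k) {
  check_k_codec(k);
  return arcs_from_id(id_from_double(id, k), k);
}

// [[Rcpp::export]]
double canonical_id_cpp(double id, int k) {
  check_k_codec(k);
  return (double)canonical_min(id_from_double(id, k), k);
}

// [[Rcpp::export]]
bool is_isomorphic_cpp(int n, IntegerMatrix arcs1, IntegerMatrix arcs2) {
  if (n < 1 || n > 8) stop("isomorphism testing supports 1..8 nodes");
  if (n == 1) return true;
  if (arcs1.nrow() != arcs2.nrow()) return false;
  return iso_ids(id_from_arcs(arcs1, n), id_from_arcs(arcs2, n), n);
}

// [[Rcpp::export]]
bool weakly_connected_cpp(int n, IntegerMatrix arcs) {
  if (n <= 1) return true;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  int comps = n;
  for (int r = 0; r < arcs.nrow(); ++r) {
    int a = find(arcs(r, 0)), b = find(arcs(r, 1));
    if (a != b) { parent[a] = b; --comps; }
  }
  return comps == 1;
}

// [[Rcpp::export]]
bool id_connected_cpp(double id, int k) {
  check_k_codec(k);
  return id_connected(id_from_double(id, k), k);
}
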