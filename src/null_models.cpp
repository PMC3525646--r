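#include "core.h"
using namespace Rcpp;

uint64_t id_from_double(double id, int k);

namespace {

struct ArcGraph {
  int n;
  std::vector<std::pair<int, int>> arcs;
  std::unordered_set<int64_t> have;

  ArcGraph(int n_, const IntegerMatrix& m) : n(n_) {
    arcs.reserve(m.nrow());
    for (int r = 0; r < m.nrow(); ++r) {
      arcs.push_back({m(r, 0), m(r, 1)});
      have.insert(key(m(r, 0), m(r, 1)));
    }
  }
  int64_t key(int u, int v) const { return (int64_t)u * n + v; }
  bool has(int u, int v) const { return have.count(key(u, v)) > 0; }

  IntegerMatrix to_matrix() const {
    IntegerMatrix m((int)arcs.size(), 2);
    for (size_t r = 0; r < arcs.size(); ++r) {
      m(r, 0) = arcs[r].first;
      m(r, 1) = arcs[r].second;
    }
    return m;
  }
};

enum Method { M_F, M_NR, M_GC, M_LC };

Method parse_method(const std::string& s) {
  if (s == "f") return M_F;
  if (s == "nr") return M_NR;
  if (s == "gc") return M_GC;
  if (s == "lc") return M_LC;
  stop("unknown switching method '%s'", s);
}

// One switching proposal: pick arcs (u->v), (x->y); replace by (u->y), (x->v)
// unless a loop or parallel arc would arise or the method's reciprocal-edge
// conservation law would be violated.  Rejected proposals leave g unchanged.
void propose(ArcGraph& g, Method method, Rng& rng) {
  size_t m = g.arcs.size();
  if (m < 2) return;
  size_t i = (size_t)rng.below(m), j = (size_t)rng.below(m);
  if (i == j) return;
  int u = g.arcs[i].first, v = g.arcs[i].second;
  int x = g.arcs[j].first, y = g.arcs[j].second;
  if (u == y || x == v) return;          // would create a loop
  if (v == y || u == x) return;          // exchange is a no-op
  // parallel-arc check: the removed arcs (u,v),(x,y) never coincide with the
  // candidates (u,y),(x,v) at this point, so plain membership suffices
  if (g.has(u, y) || g.has(x, v)) return;
  bool ruv = g.has(v, u), rxy = g.has(y, x);   // reciprocal partners removed
  bool ruy = g.has(y, u), rxv = g.has(v, x);   // reciprocal partners created
  if (method == M_F) {
    if (ruv || rxy) return;  // bidirectional pairs are frozen
    if (ruy || rxv) return;  // and no new ones may form
  } else if (method == M_GC) {
    int delta = (int)ruy + (int)rxv - (int)ruv - (int)rxy;
    if (delta != 0) return;  // global reciprocal-pair count conserved
  } else if (method == M_LC) {
    // per-vertex reciprocal degree conserved
    int d[4] = {0, 0, 0, 0};
    int vs[4] = {u, v, x, y};
    auto bump = [&](int w, int by) {
      for (int t = 0; t < 4; ++t)
        if (vs[t] == w) d[t] += by;
    };
    if (ruv) { bump(u, -1); bump(v, -1); }
    if (rxy) { bump(x, -1); bump(y, -1); }
    if (ruy) { bump(u, 1); bump(y, 1); }
    if (rxv) { bump(x, 1); bump(v, 1); }
    for (int t = 0; t < 4; ++t)
      if (d[t] != 0) return;
  }
  g.have.erase(g.key(u, v));
  g.have.erase(g.key(x, y));
  g.arcs[i] = {u, y};
  g.arcs[j] = {x, v};
  g.have.insert(g.key(u, y));
  g.have.insert(g.key(x, v));
}

}  // namespace

// Run the switching chain from the input graph through `n_segments` segments
// of ceil(switches_per_arc * m) proposals each, and return the final state.
// Segment j draws from an independent stream seeded by (seed, j), so the
// chain is reproducible segment-by-segment regardless of which worker
// replays it: comparison graph i is the state after burnin + i segments.
// [[Rcpp::export]]
IntegerMatrix switch_chain_cpp(int n, IntegerMatrix arcs, std::string method,
                               double switches_per_arc, int n_segments, double seed) {
  Method mth = parse_method(method);
  ArcGraph g(n, arcs);
  int64_t per_seg = (int64_t)std::ceil(switches_per_arc * (double)g.arcs.size());
  for (int j = 1; j <= n_segments; ++j) {
    Rng rng(stream_seed((uint64_t)seed, (uint64_t)j));
    for (int64_t t = 0; t < per_seg; ++t) propose(g, mth, rng);
    if (j % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return g.to_matrix();
}

// Per-vertex (total out-degree, total in-degree, reciprocal-pair count).
// [[Rcpp::export]]
IntegerMatrix degree_profile_cpp(int n, IntegerMatrix arcs) {
  IntegerMatrix prof(n, 3);
  ArcGraph g(n, arcs);
  for (auto& a : g.arcs) {
    prof(a.first, 0) += 1;
    prof(a.second, 1) += 1;
    if (g.has(a.second, a.first)) prof(a.first, 2) += 1;
  }
  return prof;
}

// Uniform local-constant sampler: configuration-model stub matching with
// three stub types (pure-out, pure-in, reciprocal) and whole-sample rejection
// of any loop, parallel arc, or accidental reciprocal pair.  Every simple
// realization of the profile corresponds to the same number of stub
// matchings, so accepted samples are uniform over the realization set.
// [[Rcpp::export]]
IntegerMatrix sample_ulc_cpp(int n, IntegerMatrix arcs, double seed, int index,
                             int max_tries) {
  IntegerMatrix prof = degree_profile_cpp(n, arcs);
  std::vector<int> pure_out(n), pure_in(n), recip(n);
  for (int i = 0; i < n; ++i) {
    recip[i] = prof(i, 2);
    pure_out[i] = prof(i, 0) - recip[i];
    pure_in[i] = prof(i, 1) - recip[i];
  }
  std::vector<int> ostubs, istubs, rstubs;
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < pure_out[i]; ++t) ostubs.push_back(i);
    for (int t = 0; t < pure_in[i]; ++t) istubs.push_back(i);
    for (int t = 0; t < recip[i]; ++t) rstubs.push_back(i);
  }
  Rng rng(stream_seed((uint64_t)seed, (uint64_t)index));
  std::unordered_set<int64_t> have;
  std::vector<std::pair<int, int>> out;
  for (int attempt = 0; attempt < max_tries; ++attempt) {
    have.clear();
    out.clear();
    bool ok = true;
    // reciprocal pairs: random perfect matching of reciprocal stubs
    rng.shuffle(rstubs);
    for (size_t t = 0; ok && t + 1 < rstubs.size(); t += 2) {
      int a = rstubs[t], b = rstubs[t + 1];
      if (a == b || have.count((int64_t)a * n + b)) { ok = false; break; }
      have.insert((int64_t)a * n + b);
      have.insert((int64_t)b * n + a);
      out.push_back({a, b});
      out.push_back({b, a});
    }
    // single arcs: random matching of pure-out stubs to pure-in stubs
    if (ok) {
      rng.shuffle(istubs);
      for (size_t t = 0; t < ostubs.size(); ++t) {
        int u = ostubs[t], v = istubs[t];
        // reject loops, parallels, and arcs that would form a reciprocal pair
        if (u == v || have.count((int64_t)u * n + v) ||
            have.count((int64_t)v * n + u)) { ok = false; break; }
        have.insert((int64_t)u * n + v);
        out.push_back({u, v});
      }
    }
    if (ok) {
      IntegerMatrix m((int)out.size(), 2);
      for (size_t r = 0; r < out.size(); ++r) {
        m(r, 0) = out[r].first;
        m(r, 1) = out[r].second;
      }
      return m;
    }
    if (attempt % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  stop("uniform sampling gave up after %d attempts; the degree profile is too constrained -- consider a switching method instead", max_tries);
}

// All loop-free simple digraphs on n nodes realizing the given profile,
// returned as full-graph encodings; brute-force over all 2^(n(n-1)) arc sets.
// [[Rcpp::export]]
NumericVector enumerate_profile_realizations_cpp(IntegerMatrix prof) {
  int n = prof.nrow();
  if (n < 2 || n > 5) stop("realization enumeration supports 2..5 nodes");
  int nb = n * (n - 1);
  std::vector<uint64_t> hits;
  for (uint32_t p = 0; p < (1U << nb); ++p) {
    uint64_t id = unpack_id(p, n);
    bool ok = true;
    for (int i = 0; ok && i < n; ++i) {
      int dout = 0, din = 0, drec = 0;
      for (int j = 0; j < n; ++j) {
        if (i == j) continue;
        bool fw = get_bit(id, n, i, j), bw = get_bit(id, n, j, i);
        if (fw) ++dout;
        if (bw) ++din;
        if (fw && bw) ++drec;
      }
      if (dout != prof(i, 0) || din != prof(i, 1) || drec != prof(i, 2)) ok = false;
    }
    if (ok) hits.push_back(id);
  }
  NumericVector out((R_xlen_t)hits.size());
  for (size_t i = 0; i < hits.size(); ++i) out[i] = (double)hits[i];
  return out;
}
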