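---
title: "Motif detection by exhaustive census: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif detection by exhaustive census: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmotif)
```

## The statistical model

A k-node network motif is a weakly connected digraph class that is
over-represented among the induced k-node subgraphs of an input network G,
relative to an ensemble of random "comparison" networks with the same
per-vertex in- and out-degrees. For each class H the package reports:

* **frequency** $f_G(H)$: the number of induced copies of H in G
  (overlapping copies all count);
* **concentration**: $f_G(H)$ divided by the total number of weakly
  connected induced k-subgraphs of G;
* **empirical p-value**: the fraction of the M comparison graphs containing
  at least $f_G(H)$ copies of H. Classes never seen in a comparison graph
  contribute a count of zero, so a class absent from the input has p = 1 by
  construction;
* **Z-score**: $(f_G(H) - \hat\mu) / \hat\sigma$, where $\hat\mu$ and
  $\hat\sigma$ are the sample mean and sample standard deviation (denominator
  $M-1$) of the comparison counts. No normality is implied; the score is
  reported for comparability with other tools, and it is `NA` whenever
  $\hat\sigma = 0$ — never $\pm\infty$. Degenerate nulls are the norm rather
  than the exception at k = 6, where the number of classes explodes
  (1,530,843 connected 6-node digraph classes) and most observed classes
  occur a handful of times;
* **motif call**: `p_value < alpha` *and* `frequency >= min_frequency`,
  with a strict inequality at the threshold. Both statistics are always
  reported regardless of the call, because frequency- and
  concentration-based decisions can genuinely disagree.

The default p-value is a pure ensemble proportion $r/M$. The alternative
$(r+1)/(M+1)$ convention, which counts the input network as one member of
its own null ensemble and can never return exactly zero, is available via
`p_add_one = TRUE` (`--p-add-one` on the command line). No multiple-testing
correction is applied; the verbose count matrix exists precisely so users
can apply their own downstream analysis.

## Classifying subgraphs without an isomorphism package

Every k-node subgraph encountered must be assigned to its isomorphism
class, typically billions of times per run, so this is the step worth
engineering. A k-node digraph is encoded by reading its adjacency matrix
row-major as a binary number, most significant bit first (the graphID; the
feed-forward loop is 38, the complete triad 238). The canonical ID of a
class is the minimum graphID over all $k!$ relabelings.

**k &le; 5: full tables.** The canonical ID of *every* loop-free k-node
digraph is precomputed into a flat array indexed by the packed
off-diagonal bits ($2^{k(k-1)}$ entries: 64, 4096, ~10^6). Rather than
minimizing over $k!$ relabelings per entry, the build flood-fills
isomorphism orbits: from each unvisited encoding it applies the adjacent
transpositions of $S_k$ breadth-first and assigns the orbit minimum to all
members, costing $O(2^{k(k-1)} \cdot k)$ relabelings in total. The k = 5
build takes about two seconds and is cached per session in memory. A file
cache was considered and rejected: the build cost is too small to justify
binary state on disk. k = 6 has $2^{30}$ encodings per the same scheme and
over a billion table entries, which is why no k = 6 table exists.

**k = 6: decks of cards.** Deleting one vertex of a 6-node graph leaves a
5-node *card*, classified through the k = 5 table; the sorted multiset of
the six cards is the graph's *deck*. Isomorphic graphs have equal decks,
and — this is a computational reading of the digraph Reconstruction
Conjecture — non-isomorphic 6-node digraphs almost always have different
decks. The census keeps a list of entries keyed by a 64-bit hash of the
deck; within a hash bucket, candidate and entry are compared first by full
deck and then by an explicit backtracking isomorphism test (pruned by
per-vertex out/in/reciprocal degree triples) against the stored
representative. The fallback test makes classification exact without any
table of exceptional cases: a deck-sharing non-isomorphic pair merely costs
one failed comparison. Such pairs do exist — `find_deck_collision()`
searches random 6-node tournaments, where deck-sharing non-isomorphic pairs
concentrate (tournaments are the classical counterexamples to
reconstruction), and typically finds one within a few dozen draws. An
exhaustive check over all 56 six-node tournament classes shows exactly four
deck-sharing pairs among them.

The stored representative (and hence the `id` column of a k = 6 report) is
the first subgraph of its class encountered in the input network, not
necessarily in canonical form; `canonical_id()` converts if needed. Only
classes present in the input network are tracked: subgraphs of comparison
graphs whose class never occurred in G are deliberately ignored (they could
only ever push their own p-value to 1).

## Enumerating subgraphs

Connected induced k-subgraphs are enumerated by rooted composition
enumeration: roots are processed in ascending label order; for each root,
the remaining $k-1$ vertices are chosen as compositions over successive
neighborhood levels (treating arcs as undirected adjacency), with all
candidate children of a level marked visited before subsets are chosen so
that each subset arises from exactly one BFS layering; vertices already
used as roots are excluded. Each connected subset is therefore produced
exactly once, rooted at its minimum vertex. The suite verifies this against
a brute-force census (all $\binom{n}{k}$ subsets, connectivity filter,
exhaustive canonicalization) class-for-class on hundreds of random graphs,
including the deck-based k = 6 path.

## The null models

All methods preserve every vertex's total in- and out-degree. They differ
in their treatment of bidirectional (reciprocal) edges, which in biological
networks are both common and structurally meaningful:

| method | reciprocal-edge law |
|--------|---------------------|
| `f`    | the reciprocal pair *set* is frozen; only single arcs move |
| `nr`   | no constraint |
| `gc`   | the *total* number of reciprocal pairs is conserved |
| `lc`   | each vertex's reciprocal degree is conserved |
| `ulc`  | as `lc`, but sampled uniformly at random |

The switching methods run a Markov chain: two arcs $(u\to v, x\to y)$ are
chosen at random and replaced by $(u\to y, x\to v)$ unless a loop or
parallel arc would arise or the method's conservation law would be violated
(rejection, in the Metropolis style — for `gc` and `lc` the law is enforced
by rejecting violating proposals rather than by compensating double-moves,
the simplest contract that satisfies the conservation law). One chain
*segment* is $\lceil s \cdot m \rceil$ proposals, with $s$ = 3 proposed
exchanges per arc by default, a widespread convention for degree-preserving
randomization; comparison graph $i$ is the chain state after
$\text{burnin} + i$ segments. Burnin discards the leading states so the
ensemble does not start at the input network itself. Setting
`switches_per_arc = 0` freezes the chain, a handy debugging mode in which
every class has p = 1 exactly.

Chains sample the realization set non-uniformly. The `ulc` method instead
draws uniformly: each vertex carries pure-out, pure-in and reciprocal
stubs; reciprocal stubs are paired by a random perfect matching and
pure-out stubs are matched to pure-in stubs at random; the *whole sample*
is rejected if any loop, parallel arc or accidental reciprocal pair arises.
Every simple realization corresponds to the same number
($\prod_i r_i! \, o_i! \, \iota_i!$) of stub matchings, so accepted samples
are exactly uniform — the suite verifies this by chi-square against
brute-force-enumerated realization sets. The price is an acceptance
probability that decays roughly exponentially with the arc count: instant
for sparse profiles (10 nodes at arc density 0.2), hopeless for dense ones,
at which point the sampler raises an error suggesting a switching method.
This is an inherent property of whole-sample rejection, not a tunable; the
test suite accordingly exercises `ulc` on sparse profiles only.

### Reproducibility and parallelism

Every source of randomness on the compiled side uses a deterministic
64-bit stream (splitmix64) — never the platform's `rand` or a
distribution object with unspecified cross-platform behavior. Chain segment
$j$ draws from a stream seeded by (master seed, $j$), so comparison graph
$i$ is reproducible by replaying segments $1..\text{burnin}+i$ from the
input graph, with no shared chain state between workers; `ulc` draw $i$
similarly has its own stream. Replaying costs $O(M^2)$ proposals over a
whole run, which is negligible at realistic ensemble sizes and buys an
unconditional guarantee: reports are byte-identical for any thread count at
a fixed seed (verified for 1, 2 and 4 threads). The input census always
runs in serial; comparison censuses are farmed one-graph-per-task to a
`parallel::mclapply` pool.

## Enumeration of isomorphism classes

`enumerate_connected_classes()` counts weakly connected classes two
independent ways: exhaustively (orbit flood-fill over all labeled graphs;
directed k &le; 5, undirected k &le; 6) and by growth (every connected
graph has a non-cut vertex, so attaching a new vertex with every nonzero
neighborhood to each connected $(k-1)$-class reaches every $k$-class;
candidates are canonicalized and deduplicated). The two strategies agree
wherever both apply, and reproduce the known sequences: 13, 199, 9364
connected digraph classes for k = 3..5 (OEIS A003085) and 2, 6, 21, 112,
853 connected undirected classes for k = 3..7 (A001349). Directed k = 6 is
reachable only by growth and costs hours with per-candidate exhaustive
canonicalization; it ships as the optional script
`scripts/enumerate-digraphs-k6.R` rather than a suite test.

## Fixtures and what the tests do (and do not) show

`generate_fixture()` produces the study networks: complete digraphs (the
analytic check: a census of $K_n$ has a single class with $\binom{n}{k}$
copies — 19,600 complete triads for $n=50, k=3$; note that a loop-free
complete digraph on 50 vertices has exactly $50 \cdot 49 = 2450$ arcs),
seeded Erdős–Rényi-style digraphs, and motif-implanted networks in which
disjoint vertex triples are cleared and overwritten with copies of a chosen
3-node class, guaranteeing at least that many induced copies. Implanted
networks emulate the one property motif detection targets — a subgraph
class enriched beyond degree-sequence expectation — but none of the other
structure of real biological networks (degree correlations, modularity,
hubs), so passing tests demonstrate correctness of the census and
statistics, not biological validity of any particular motif call. Oracle
tests run on graphs of up to 12–16 nodes and ensembles of 5–100 comparison
graphs; these sizes keep the brute-force oracles exact and the suite quick,
and nothing in the algorithms is size-specific below the documented bounds.

## Numerical and edge-case choices

* Graph IDs up to k = 6 (36 bits) exceed 32-bit integers and are carried as
  R doubles (exact up to $2^{53}$).
* Loops in input are stripped with a warning, duplicate arcs deduplicated
  with a warning; an edge list that parses to an empty graph is an error.
* Ties in the report are broken by ascending ID after descending frequency,
  so output is bit-stable.
* A proposal that would merely swap an arc pair into itself (shared head or
  shared tail) is counted as a rejection; the 3-cycle, whose every proposal
  is invalid, therefore never moves — the chain is simply stuck at a
  one-point realization set, which is correct.
* `census_bruteforce()` refuses graphs with more than 15 nodes; it exists
  as a test oracle, not a production path.

## Known limitations

* k is capped at 6 by design; the classification tables and decks do not
  extend further without a different preprocessing scheme.
* Colored/weighted graphs, self-loops and multigraphs are out of scope.
* The switching chains sample realizations non-uniformly (a known property
  of switching randomization); `ulc` is exact but only practical on sparse
  profiles.
* Empirical p-values are granular at $1/M$; in the k = 6 regime many
  classes tie at p = 1 and distinguishing them requires a larger ensemble,
  which is the motivation for the parallel execution path.
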