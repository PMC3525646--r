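#' Configuration of the comparison-graph ensemble
#'
#' A comparison ("similar") graph has the same vertices and the same
#' per-vertex in- and out-degrees as the input network. Five generation
#' methods are available, differing in how bidirectional (reciprocal) edges
#' are treated:
#'
#' * `"f"` -- fixed bidirectional edges: reciprocal pairs are frozen; only
#'   non-reciprocal arcs switch and no new reciprocal pair may form;
#' * `"nr"` -- no regard: arcs switch freely;
#' * `"gc"` -- global constant: the total number of reciprocal pairs is
#'   conserved (proposals changing it are rejected);
#' * `"lc"` -- local constant: each vertex's reciprocal degree is conserved;
#' * `"ulc"` -- uniform local constant: graphs are drawn uniformly at random
#'   from all realizations of the full (out, in, reciprocal) degree profile
#'   via configuration-model stub matching with rejection (can be very slow
#'   on constrained profiles; see [sample_uniform_lc()]).
#'
#' The switching methods run a Markov chain of arc exchanges
#' `(u->v, x->y) => (u->y, x->v)`, each applied only if no loop or parallel
#' arc would arise. Comparison graph `i` is the chain state after
#' `burnin + i` segments of `ceil(switches_per_arc * n_arcs)` proposals; the
#' first `burnin` states are discarded so the ensemble does not start at the
#' input network. Every segment draws from an independent stream seeded by
#' `(seed, segment)`, so any worker can reproduce graph `i` from the
#' configuration alone.
#'
#' @param method one of `"f"`, `"nr"`, `"gc"`, `"lc"`, `"ulc"`.
#' @param n_comparison ensemble size M (>= 1).
#' @param burnin number of leading chain states to discard (>= 0).
#' @param switches_per_arc proposed exchanges per arc per chain segment;
#'   the default 3 is the usual convention for degree-preserving switching.
#'   `0` yields an ensemble of copies of the input (useful for debugging).
#' @param seed integer master seed.
#' @return A list of class `"null_model_config"`.
#' @export
null_model_config <- function(method = c("lc", "f", "nr", "gc", "ulc"),
                              n_comparison = 100L, burnin = 0L,
                              switches_per_arc = 3, seed = 1L) {
  method <- match.arg(method)
  n_comparison <- as.integer(n_comparison)
  burnin <- as.integer(burnin)
  if (n_comparison < 1L) stop("`n_comparison` must be at least 1")
  if (burnin < 0L) stop("`burnin` must be non-negative")
  if (switches_per_arc < 0) stop("`switches_per_arc` must be non-negative")
  structure(list(method = method, n_comparison = n_comparison, burnin = burnin,
                 switches_per_arc = switches_per_arc, seed = as.numeric(seed)),
            class = "null_model_config")
}

#' Generate one comparison graph
#'
#' Reproducible from `(cfg$seed, index)` alone: for the switching methods the
#' chain is replayed deterministically through `cfg$burnin + index` segments;
#' for `"ulc"` draw `index` comes from its own independent stream. Parallel
#' workers therefore need no shared state and produce the same ensemble as a
#' serial run.
#'
#' @param g the input [digraph()].
#' @param cfg a [null_model_config()].
#' @param index which comparison graph (1-based, `<= cfg$n_comparison`).
#' @return A [digraph()] with the same per-vertex in/out degrees as `g`.
#' @export
generate_comparison <- function(g, cfg, index) {
  stopifnot(inherits(g, "digraph"), inherits(cfg, "null_model_config"))
  index <- as.integer(index)
  if (index < 1L) stop("`index` must be at least 1")
  if (cfg$method == "ulc") {
    arcs <- sample_ulc_cpp(g$n_nodes, arcs0(g), cfg$seed,
                           cfg$burnin + index, 2000000L)
  } else {
    arcs <- switch_chain_cpp(g$n_nodes, arcs0(g), cfg$method,
                             cfg$switches_per_arc, cfg$burnin + index, cfg$seed)
  }
  digraph(arcs + 1L, n_nodes = g$n_nodes)
}

#' Draw one uniform sample of the local-constant null model
#'
#' Implements the uniform local-constant mode as a variant of the
#' configuration model with three stub types per vertex: pure-out, pure-in
#' and reciprocal. Reciprocal stubs are paired by a random perfect matching
#' and pure-out stubs are matched to pure-in stubs at random; the whole
#' sample is rejected and redrawn if any loop, parallel arc or accidental
#' reciprocal pair arises. Every simple realization of the profile
#' corresponds to the same number of stub matchings, so accepted samples are
#' uniform over the realization set.
#'
#' @param g the input [digraph()] (its degree profile is the target).
#' @param seed integer seed.
#' @param index stream index, so that successive draws are independent.
#' @param max_tries rejection budget; on very constrained profiles the
#'   sampler gives up with an error suggesting a switching method instead.
#' @return A [digraph()] with exactly the same (out, in, recip) profile.
#' @export
sample_uniform_lc <- function(g, seed = 1L, index = 1L, max_tries = 100000L) {
  stopifnot(inherits(g, "digraph"))
  arcs <- sample_ulc_cpp(g$n_nodes, arcs0(g), as.numeric(seed),
                         as.integer(index), as.integer(max_tries))
  digraph(arcs + 1L, n_nodes = g$n_nodes)
}

#' Enumerate all realizations of a degree profile
#'
#' Brute-force oracle over all loop-free labeled digraphs on `n <= 5` nodes;
#' used to verify that [sample_uniform_lc()] is statistically uniform.
#'
#' @param profile an integer matrix as returned by [degree_profile()].
#' @return Numeric vector of full-graph IDs (n-node encoding) of every
#'   labeled digraph realizing the profile.
#' @export
enumerate_profile_realizations <- function(profile) {
  storage.mode(profile) <- "integer"
  enumerate_profile_realizations_cpp(profile)
}
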