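# small named graphs used across the suite

feed_forward_loop <- function() digraph(rbind(c(2, 1), c(3, 1), c(3, 2)))

cycle_digraph <- function(n) {
  digraph(cbind(seq_len(n), c(seq_len(n)[-1], 1L)), n_nodes = n)
}

path_digraph <- function(n) {
  digraph(cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L), n_nodes = n)
}

complete_digraph <- function(n) generate_fixture("complete", n = n)

random_digraph <- function(n, density, seed) {
  # tiny sparse draws can come up empty; walk the seed until non-empty
  for (s in seed + 1000000L * (0:19)) {
    g <- tryCatch(generate_fixture("random", n = n, density = density, seed = s),
                  error = function(e) NULL)
    if (!is.null(g)) return(g)
  }
  stop("could not draw a non-empty random graph")
}

# relabel a digraph by a permutation (vertex i becomes perm[i])
relabel <- function(g, perm) {
  digraph(cbind(perm[g$arcs[, 1L]], perm[g$arcs[, 2L]]), n_nodes = g$n_nodes)
}

# sorted canonical class ids of a k = 6 census (whose ids are representatives)
canonicalize_census6 <- function(cen) {
  ord <- order(vapply(cen$ids, canonical_id, numeric(1), k = 6L))
  list(ids = vapply(cen$ids, canonical_id, numeric(1), k = 6L)[ord],
       counts = cen$counts[ord])
}

# reciprocal arc pairs of a digraph, as a sorted key vector
recip_pairs <- function(g) {
  key <- paste(g$arcs[, 1L], g$arcs[, 2L])
  rev_key <- paste(g$arcs[, 2L], g$arcs[, 1L])
  mutual <- key[key %in% rev_key]
  sort(mutual)
}
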