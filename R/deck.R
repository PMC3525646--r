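#' Deck of a 6-node digraph
#'
#' The deck of a 6-node graph is the sorted multiset of canonical IDs of its
#' six vertex-deleted 5-node induced subgraphs (its "cards", in Reconstruction
#' Conjecture vocabulary). Isomorphic graphs always have equal decks, and for
#' 6-node digraphs the converse holds up to a short list of exceptional
#' pairs, which is what makes the deck a practical classification key for the
#' 6-node census: two subgraphs with equal decks are isomorphic in all but
#' vanishingly rare cases, and those are resolved by an explicit isomorphism
#' test (see [census()]).
#'
#' @param g a [digraph()] with exactly 6 nodes.
#' @param table the k = 5 canonical table; built (or fetched from the session
#'   cache) automatically by default.
#' @return An object of class `"deck"`: numeric vector of the 6 card IDs in
#'   ascending order, with attribute `hash` (a deterministic 64-bit mix of
#'   the sorted cards, printed as 16 hex digits) used to bucket decks during
#'   the census.
#' @export
compute_deck <- function(g, table = build_canon_table(5)) {
  stopifnot(inherits(g, "digraph"), inherits(table, "canon_table"))
  if (g$n_nodes != 6L) stop("decks are defined for 6-node graphs")
  if (table$k != 5L) stop("`table` must be the k = 5 canonical table")
  res <- compute_deck_cpp(arcs0(g), table$labels)
  structure(res$cards, hash = res$hash, class = "deck")
}

#' @export
print.deck <- function(x, ...) {
  cat("deck of 5-node cards:", paste(format(unclass(x), scientific = FALSE), collapse = " "),
      sprintf("\nhash: %s\n", attr(x, "hash")))
  invisible(x)
}

#' Deck hash
#'
#' @param d a [compute_deck()] result.
#' @return The 64-bit deck hash as a 16-hex-digit string. Deterministic across
#'   runs and platforms; equal decks always hash equally, and distinct decks
#'   may collide (collisions are resolved by full deck comparison and an
#'   isomorphism check during the census).
#' @export
deck_hash <- function(d) {
  stopifnot(inherits(d, "deck"))
  attr(d, "hash")
}

#' Search for a deck collision between non-isomorphic 6-node digraphs
#'
#' Vertex-deleted decks do not quite determine a 6-node digraph up to
#' isomorphism: a small number of exceptional pairs share a deck without
#' being isomorphic, which is why the 6-node census backs deck comparison
#' with an isomorphism test. This search documents that such pairs exist. It
#' draws random 6-node digraphs and (a) checks each graph against its
#' converse, whose deck is equal whenever the card multiset is closed under
#' arc reversal, and (b) keeps a birthday table of observed decks.
#'
#' @param seed integer seed for the search stream.
#' @param max_tries number of random graphs to inspect.
#' @param table the k = 5 canonical table.
#' @return `NULL` if no collision was found within `max_tries`; otherwise a
#'   list with digraphs `g1`, `g2` (equal decks, non-isomorphic) and the
#'   number of draws used.
#' @export
find_deck_collision <- function(seed = 1L, max_tries = 20000L,
                                table = build_canon_table(5)) {
  stopifnot(inherits(table, "canon_table"), table$k == 5L)
  res <- find_deck_collision_cpp(table$labels, as.numeric(seed), as.integer(max_tries))
  if (length(res) == 0L) return(NULL)
  list(g1 = decode_graph_id(res$g1, 6L),
       g2 = decode_graph_id(res$g2, 6L),
       tries = res$tries)
}
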