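# session-level cache for canonical tables (built once per k per session)
.canon_cache <- new.env(parent = emptyenv())

#' Build the canonical-label table for k-node digraphs
#'
#' Pretreatment phase of the census: the canonical ID of every loop-free
#' k-node digraph is precomputed so that classifying a subgraph costs one
#' array lookup instead of an isomorphism computation. The table is indexed by
#' the packed off-diagonal bits of the graph ID, so it has `2^(k*(k-1))`
#' entries (64 at k = 3, 4096 at k = 4, 2^20 at k = 5).
#'
#' The build walks isomorphism orbits by flood-fill: from each unvisited ID it
#' applies the adjacent-transposition generators of the symmetric group
#' breadth-first and assigns the orbit minimum to every member. This avoids
#' the k!-per-entry cost of naive minimization and makes the k = 5 table a
#' matter of seconds. Tables are cached per session after first use.
#'
#' @param k subgraph size, 3..5. For k = 6 no full table is feasible (over
#'   a billion entries); the deck-based machinery in [compute_deck()] /
#'   [census()] is used instead, and requesting k = 6 here is an error.
#' @param cache use/populate the per-session cache (default `TRUE`).
#' @return An object of class `"canon_table"`: list with `k` and `labels`,
#'   an integer vector of length `2^(k*(k-1))` mapping every packed graph ID
#'   to its canonical ID.
#' @export
build_canon_table <- function(k, cache = TRUE) {
  k <- as.integer(k)
  if (identical(k, 6L))
    stop("no full canonical table is built for k = 6; 6-node subgraphs are classified via their decks (see compute_deck)")
  if (k < 3L || k > 5L) stop("canonical tables support k in 3..5")
  key <- as.character(k)
  if (cache && !is.null(.canon_cache[[key]])) return(.canon_cache[[key]])
  tab <- structure(list(k = k, labels = build_canon_table_cpp(k)),
                   class = "canon_table")
  if (cache) .canon_cache[[key]] <- tab
  tab
}

#' @export
print.canon_table <- function(x, ...) {
  cat(sprintf("canonical-label table: k = %d, %d entries, %d classes\n",
              x$k, length(x$labels), length(unique(x$labels))))
  invisible(x)
}

#' Look up the canonical ID of a graph ID
#'
#' O(1) table lookup; agrees with [canonical_id()] on every valid ID.
#'
#' @param table a [build_canon_table()] result.
#' @param id a graph ID with matching `k`.
#' @return The canonical ID, as a numeric scalar.
#' @export
canon_lookup <- function(table, id) {
  stopifnot(inherits(table, "canon_table"))
  canon_lookup_cpp(table$labels, as.numeric(id), table$k)
}

#' Enumerate connected isomorphism classes of small graphs
#'
#' Counts (and lists) the weakly connected isomorphism classes of loop-free
#' k-node digraphs, or of k-node undirected graphs encoded as symmetric
#' digraphs. Two independent strategies are available:
#'
#' * `"exhaustive"`: orbit flood-fill over every labeled graph
#'   (directed k <= 5, undirected k <= 6);
#' * `"growth"`: isomorph-free generation by extending each connected
#'   (k-1)-class with one new vertex carrying every nonzero neighborhood,
#'   then canonicalizing and deduplicating (directed k <= 6, undirected
#'   k <= 7). This is sound because every weakly connected graph has a
#'   non-cut vertex (any leaf of a spanning tree).
#'
#' The directed counts are OEIS A003085 (13, 199, 9364, ... for k = 3, 4, 5)
#' and the undirected counts are A001349 (2, 6, 21, 112, 853 for k = 3..7).
#' Directed k = 6 (1,530,843 classes) is only reachable via `"growth"` and
#' takes a long time; it is not computed by default anywhere in the package.
#'
#' @param k node count.
#' @param directed enumerate digraph classes (default) or undirected classes.
#' @param method `"auto"` picks exhaustive enumeration where feasible and
#'   growth otherwise.
#' @return Numeric vector of canonical IDs of the connected classes (its
#'   `length()` is the class count).
#' @examples
#' length(enumerate_connected_classes(3))                    # 13
#' length(enumerate_connected_classes(4, directed = FALSE))  # 6
#' @export
enumerate_connected_classes <- function(k, directed = TRUE,
                                        method = c("auto", "exhaustive", "growth")) {
  k <- as.integer(k)
  method <- match.arg(method)
  if (k < 2L) stop("k must be at least 2")
  max_k <- if (directed) 6L else 7L
  if (k > max_k)
    stop(sprintf("enumeration supports %s k <= %d",
                 if (directed) "directed" else "undirected", max_k))
  if (method == "auto")
    method <- if ((directed && k <= 5L) || (!directed && k <= 6L)) "exhaustive" else "growth"
  if (method == "exhaustive")
    exhaustive_connected_classes_cpp(k, directed)
  else
    grow_connected_classes_cpp(k, directed)
}
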