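#' Enumerate connected induced k-node subgraphs
#'
#' Yields every vertex subset of size `k` that induces a weakly connected
#' subgraph, exactly once, using rooted composition enumeration: each root is
#' processed in ascending label order, the remaining k-1 vertices are chosen
#' as compositions over breadth-first neighborhood levels among vertices not
#' yet used as roots, and the root is then retired. Mainly exposed for
#' testing; [census()] consumes the stream internally.
#'
#' @param g a [digraph()].
#' @param k subgraph size, 3..6.
#' @param max_subsets guard against materializing huge streams.
#' @return Integer matrix, one row per subset, columns sorted ascending.
#'   `k > n_nodes(g)` yields zero rows (not an error).
#' @export
enumerate_connected_subgraphs <- function(g, k, max_subsets = 1e6) {
  stopifnot(inherits(g, "digraph"))
  k <- as.integer(k)
  if (k < 2L || k > 6L) stop("k must be in 2..6")
  enumerate_subsets_cpp(g$n_nodes, arcs0(g), k, max_subsets) + 1L
}

new_census_result <- function(k, ids, counts, total) {
  ord <- order(ids)
  structure(list(k = k, ids = ids[ord], counts = counts[ord], total = total),
            class = "census_result")
}

#' Subgraph census of a digraph
#'
#' Counts every weakly connected induced k-node subgraph of `g` by
#' isomorphism class (distinct copies may overlap). For k <= 5, each subgraph
#' is classified by an O(1) lookup in the precomputed canonical table. For
#' k = 6 no full table is feasible, so subgraphs are classified by their deck
#' of 5-node cards: a two-level search (deck hash, then full deck, then an
#' explicit isomorphism test against the stored representative) assigns each
#' subgraph to a class; the stored representative is the first subgraph of
#' its class encountered in the graph, not necessarily in canonical form.
#'
#' @param g a [digraph()].
#' @param k subgraph size, 3..6.
#' @param table the canonical table to use (k <= 5 uses the k-table, k = 6
#'   the 5-table for cards); fetched from the session cache by default.
#' @return An object of class `"census_result"`: list with `k`, `ids`
#'   (canonical class IDs for k <= 5, representative graph IDs for k = 6),
#'   `counts` (copies of each class) and `total` (all connected k-node
#'   induced subgraphs, equal to `sum(counts)`).
#' @examples
#' k4 <- generate_fixture("complete", n = 4)
#' census(k4, 3) # all four triads are the complete triad, class 238
#' @export
census <- function(g, k, table = NULL) {
  stopifnot(inherits(g, "digraph"))
  k <- as.integer(k)
  if (k < 3L || k > 6L) stop("the census supports k in 3..6")
  if (k <= 5L) {
    if (is.null(table)) table <- build_canon_table(k)
    stopifnot(inherits(table, "canon_table"), table$k == k)
    res <- census_cpp(g$n_nodes, arcs0(g), k, table$labels)
  } else {
    if (is.null(table)) table <- build_canon_table(5L)
    stopifnot(inherits(table, "canon_table"), table$k == 5L)
    res <- census6_cpp(g$n_nodes, arcs0(g), table$labels, numeric(0))
  }
  new_census_result(k, res$ids, res$counts, res$total)
}

# stage-2 census of a comparison graph: count only the classes present in the
# input network, in the given representative order; unseen classes are ignored
census_against <- function(g, k, input_census, table = NULL) {
  if (k <= 5L) {
    cen <- census(g, k, table)
    counts <- cen$counts[match(input_census$ids, cen$ids)]
    counts[is.na(counts)] <- 0
    counts
  } else {
    if (is.null(table)) table <- build_canon_table(5L)
    res <- census6_cpp(g$n_nodes, arcs0(g), table$labels, input_census$ids)
    res$counts
  }
}

#' Brute-force census oracle
#'
#' Ground truth for equivalence tests: iterates over all `choose(n, k)` vertex
#' subsets, filters by weak connectivity, and labels each subgraph by
#' exhaustive canonical minimization. Exponential in `n`; refused for graphs
#' with more than 15 nodes.
#'
#' @inheritParams census
#' @return A `"census_result"` whose `ids` are canonical IDs.
#' @export
census_bruteforce <- function(g, k) {
  stopifnot(inherits(g, "digraph"))
  k <- as.integer(k)
  res <- census_bruteforce_cpp(g$n_nodes, arcs0(g), k)
  new_census_result(k, res$ids, res$counts, res$total)
}

#' @export
print.census_result <- function(x, ...) {
  cat(sprintf("%d-node subgraph census: %d classes, %s connected subgraphs\n",
              x$k, length(x$ids), format(x$total, big.mark = ",")))
  df <- data.frame(id = format(x$ids, scientific = FALSE), count = x$counts)
  print(utils::head(df[order(-df$count), ], 10L), row.names = FALSE)
  if (length(x$ids) > 10L) cat("...\n")
  invisible(x)
}
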