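#' Construct a loop-free simple digraph
#'
#' The core graph container of the package: a set of ordered arcs `(u, v)` on
#' vertices `1..n_nodes`. Reciprocal pairs `(u, v)` and `(v, u)` are legal and
#' model one bidirectional edge. Loops are stripped with a warning and
#' duplicate arcs are deduplicated with a warning, since the motif census is
#' defined on loop-free simple digraphs only.
#'
#' @param arcs two-column matrix (or data.frame) of positive integer vertex
#'   labels; each row is one arc `u -> v`. May have zero rows.
#' @param n_nodes number of vertices; defaults to the largest label present.
#' @return An object of class `"digraph"`: a list with elements `n_nodes` and
#'   `arcs` (an integer matrix with columns `from`, `to`).
#' @examples
#' ffl <- digraph(rbind(c(1, 2), c(1, 3), c(2, 3)))
#' ffl
#' @export
digraph <- function(arcs, n_nodes = NULL) {
  if (is.data.frame(arcs)) arcs <- as.matrix(arcs)
  if (is.null(arcs) || length(arcs) == 0L) {
    arcs <- matrix(integer(0), ncol = 2L)
  }
  if (!is.matrix(arcs) || ncol(arcs) != 2L)
    stop("`arcs` must be a two-column matrix of vertex labels")
  storage.mode(arcs) <- "integer"
  if (anyNA(arcs)) stop("`arcs` contains missing values")
  if (nrow(arcs) > 0L && min(arcs) < 1L)
    stop("vertex labels must be positive integers")
  if (is.null(n_nodes)) n_nodes <- if (nrow(arcs)) max(arcs) else 0L
  n_nodes <- as.integer(n_nodes)
  if (nrow(arcs) > 0L && max(arcs) > n_nodes)
    stop("arc endpoint exceeds `n_nodes`")
  loops <- arcs[, 1L] == arcs[, 2L]
  if (any(loops)) {
    warning(sprintf("dropped %d loop arc(s); the census is defined on loop-free graphs", sum(loops)))
    arcs <- arcs[!loops, , drop = FALSE]
  }
  dup <- duplicated(arcs)
  if (any(dup)) {
    warning(sprintf("deduplicated %d parallel arc(s)", sum(dup)))
    arcs <- arcs[!dup, , drop = FALSE]
  }
  dimnames(arcs) <- list(NULL, c("from", "to"))
  structure(list(n_nodes = n_nodes, arcs = arcs), class = "digraph")
}

#' @export
print.digraph <- function(x, ...) {
  cat(sprintf("digraph: %d nodes, %d arcs\n", x$n_nodes, nrow(x$arcs)))
  invisible(x)
}

#' Number of nodes / arcs of a digraph
#' @param g a [digraph()].
#' @return Integer count.
#' @export
n_nodes <- function(g) g$n_nodes

#' @rdname n_nodes
#' @export
n_arcs <- function(g) nrow(g$arcs)

# internal: 0-based arc matrix for the compiled core
arcs0 <- function(g) {
  m <- g$arcs
  storage.mode(m) <- "integer"
  m - 1L
}

#' Test weak connectivity
#'
#' A digraph is weakly connected when the underlying undirected graph is
#' connected; motif candidates are required to be weakly connected.
#'
#' @param g a [digraph()].
#' @return `TRUE` or `FALSE`; a single-node graph is connected.
#' @export
is_weakly_connected <- function(g) {
  stopifnot(inherits(g, "digraph"))
  weakly_connected_cpp(g$n_nodes, arcs0(g))
}

#' Test digraph isomorphism
#'
#' Exact isomorphism test for small digraphs (at most 8 nodes): candidate
#' vertex maps are pruned by per-vertex (out-degree, in-degree,
#' reciprocal-degree) signatures before a backtracking search over
#' arc-preserving bijections.
#'
#' @param g1,g2 [digraph()] objects.
#' @return `TRUE` iff some bijection maps arcs onto arcs exactly. Graphs with
#'   different node counts are simply not isomorphic (`FALSE`, not an error).
#' @export
is_isomorphic <- function(g1, g2) {
  stopifnot(inherits(g1, "digraph"), inherits(g2, "digraph"))
  if (g1$n_nodes != g2$n_nodes) return(FALSE)
  if (g1$n_nodes == 0L) return(TRUE)
  is_isomorphic_cpp(g1$n_nodes, arcs0(g1), arcs0(g2))
}

#' Per-vertex degree profile
#'
#' @param g a [digraph()].
#' @return Integer matrix with one row per vertex and columns `out` (total
#'   out-degree), `in` (total in-degree) and `recip` (number of bidirectional
#'   partners, i.e. mutual arc pairs at the vertex). All null models preserve
#'   the `out` and `in` columns exactly; see [generate_comparison()] for what
#'   each method does with `recip`.
#' @export
degree_profile <- function(g) {
  stopifnot(inherits(g, "digraph"))
  prof <- degree_profile_cpp(g$n_nodes, arcs0(g))
  colnames(prof) <- c("out", "in", "recip")
  prof
}
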