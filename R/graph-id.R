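#' Encode a small digraph as its graph ID
#'
#' The graph ID of a k-node digraph is the integer obtained by reading its
#' adjacency matrix row by row as a binary number, most significant bit first
#' (the Mfinder/FanMod convention). The feed-forward loop, for example, has
#' ID 38 and the complete triad has ID 238 under this convention.
#'
#' @param g a [digraph()].
#' @param vertices the ordered vertices defining the k-node (sub)graph and the
#'   row/column order of its adjacency matrix; defaults to all vertices of `g`
#'   in label order. Arcs of `g` outside `vertices` are ignored (the induced
#'   subgraph is encoded).
#' @return A numeric scalar in `[0, 2^(k*k))` with all diagonal bits zero.
#' @examples
#' ffl <- digraph(rbind(c(2, 1), c(3, 1), c(3, 2)))
#' graph_id(ffl) # 38
#' @export
graph_id <- function(g, vertices = seq_len(g$n_nodes)) {
  stopifnot(inherits(g, "digraph"))
  k <- length(vertices)
  if (k < 2L || k > 6L) stop("graph IDs are defined for 2..6 nodes")
  if (anyDuplicated(vertices)) stop("`vertices` must be distinct")
  pos <- match(g$arcs[, 1L], vertices)
  pos2 <- match(g$arcs[, 2L], vertices)
  keep <- !is.na(pos) & !is.na(pos2)
  sub <- cbind(pos[keep], pos2[keep]) - 1L
  storage.mode(sub) <- "integer"
  graph_id_cpp(sub, as.integer(k))
}

#' Decode a graph ID back into a digraph
#'
#' Inverse of [graph_id()]: `decode_graph_id(graph_id(g), k)` reproduces `g`
#' up to the chosen vertex order.
#'
#' @param id a graph ID as produced by [graph_id()].
#' @param k the node count (2..6).
#' @return A [digraph()] on vertices `1..k`.
#' @export
decode_graph_id <- function(id, k) {
  k <- as.integer(k)
  arcs <- decode_graph_id_cpp(as.numeric(id), k)
  digraph(arcs + 1L, n_nodes = k)
}

#' Canonical graph ID by exhaustive minimization
#'
#' The canonical ID of an isomorphism class is the minimum graph ID over all
#' k! vertex relabelings, found here by brute-force search. It is constant on
#' isomorphism classes and idempotent. For bulk work use [build_canon_table()]
#' (k <= 5) or the deck-based machinery (k = 6); this function is the
#' reference implementation the faster paths are tested against.
#'
#' @inheritParams decode_graph_id
#' @return The minimal graph ID of the class, as a numeric scalar.
#' @examples
#' canonical_id(38, 3)  # the feed-forward loop is already canonical
#' canonical_id(200, 3) # a relabeling of it
#' @export
canonical_id <- function(id, k) {
  canonical_id_cpp(as.numeric(id), as.integer(k))
}

#' Flattened 0/1 adjacency-matrix string of a graph ID
#'
#' @inheritParams decode_graph_id
#' @return A string of `k*k` characters, the adjacency matrix read row-major
#'   (the binary expansion of `id`, zero-padded). Used in report output.
#' @export
adjacency_string <- function(id, k) {
  k <- as.integer(k)
  id <- as.numeric(id)
  bits <- integer(k * k)
  for (t in seq_len(k * k)) {
    bits[k * k - t + 1L] <- id %% 2
    id <- id %/% 2
  }
  paste(bits, collapse = "")
}
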