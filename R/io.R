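#' Read a digraph from a plain-text edge list
#'
#' One arc per line, two whitespace-separated integer labels `u v` meaning
#' `u -> v` (the FanMod/Kavosh edge-list lineage). Blank lines and lines
#' starting with `#` are ignored. Arbitrary integer labels are supported:
#' they are remapped to contiguous `1..n` (in sorted label order) and the
#' original labels are kept in `attr(, "labels")` for output. Loops are
#' dropped and duplicates deduplicated, each with a warning.
#'
#' @param source a file path or connection.
#' @param undirected treat each line as a bidirectional pair (expands to the
#'   two reciprocal arcs).
#' @return A [digraph()] with attribute `labels` (original label of each
#'   internal vertex).
#' @export
read_edge_list <- function(source, undirected = FALSE) {
  lines <- readLines(source, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop("empty graph: no arcs in input")
  toks <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(toks, length, integer(1)) != 2L)
  if (length(bad))
    stop(sprintf("parse error at line %d: expected two integer labels", lineno[bad[1L]]))
  u <- suppressWarnings(as.integer(vapply(toks, `[[`, character(1), 1L)))
  v <- suppressWarnings(as.integer(vapply(toks, `[[`, character(1), 2L)))
  bad <- which(is.na(u) | is.na(v))
  if (length(bad))
    stop(sprintf("parse error at line %d: non-integer vertex label", lineno[bad[1L]]))
  labels <- sort(unique(c(u, v)))
  arcs <- cbind(match(u, labels), match(v, labels))
  if (undirected) arcs <- rbind(arcs, arcs[, 2:1, drop = FALSE])
  g <- digraph(arcs, n_nodes = length(labels))
  if (nrow(g$arcs) == 0L) stop("empty graph: all arcs were loops")
  attr(g, "labels") <- labels
  g
}

#' Write a digraph as an edge list
#'
#' Inverse of [read_edge_list()]: vertices are written under their original
#' labels when the graph carries a `labels` attribute.
#'
#' @param g a [digraph()].
#' @param path file path or connection.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "digraph"))
  labels <- attr(g, "labels")
  if (is.null(labels)) labels <- seq_len(g$n_nodes)
  writeLines(paste(labels[g$arcs[, 1L]], labels[g$arcs[, 2L]]), path)
}

#' Write a motif report as tab-separated text
#'
#' One row per class: canonical ID (decimal), the k x k 0/1 adjacency-matrix
#' string, frequency, concentration, null mean, null sd, Z-score (`NA` when
#' undefined), p-value and the motif flag; rows ordered by descending
#' frequency, ties by ascending ID. Deterministic given the run seed.
#'
#' @param report a [run_detection()] result.
#' @param sink file path or connection (default standard output).
#' @export
write_report <- function(report, sink = stdout()) {
  stopifnot(inherits(report, "motif_report"))
  out <- as.data.frame(report)
  out$id <- format(out$id, scientific = FALSE, trim = TRUE)
  out$is_motif <- ifelse(out$is_motif, "1", "0")
  utils::write.table(out, sink, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
}

#' Write the verbose per-comparison count matrix
#'
#' Verbose mode exposes every count encountered during the run so that
#' independent analyses (e.g. in R: normality checks of null counts,
#' ensemble-size diagnostics) can be performed downstream: a tab-separated
#' matrix with one row per class found in the input network and one column
#' per comparison graph `1..M`.
#'
#' @inheritParams write_report
#' @export
write_verbose <- function(report, sink = stdout()) {
  stopifnot(inherits(report, "motif_report"))
  m <- attr(report, "null_counts")
  colnames(m) <- paste0("comparison_", seq_len(ncol(m)))
  utils::write.table(cbind(id = rownames(m), as.data.frame(m)), sink,
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Generate a test-network fixture
#'
#' Deterministic fixture generators used throughout the test suite and
#' examples:
#'
#' * `"complete"`: the complete digraph on `n` vertices (`n*(n-1)` arcs; all
#'   k-subsets induce the complete k-subgraph, giving a census with a single
#'   class of `choose(n, k)` copies);
#' * `"random"`: each ordered pair becomes an arc independently with
#'   probability `density`;
#' * `"implanted"`: a random background in which `motif_count` disjoint
#'   vertex triples are cleared and overwritten with copies of a chosen
#'   3-node class (default 38, the feed-forward loop), so the census count of
#'   that class is at least `motif_count`.
#'
#' @param kind one of `"complete"`, `"random"`, `"implanted"`.
#' @param n number of vertices.
#' @param density arc probability for the random background.
#' @param motif_count number of implanted copies.
#' @param motif_id 3-node class to implant.
#' @param seed integer seed (used by `"random"` and `"implanted"`).
#' @param file optional path; when given, the graph is also written as an
#'   edge list.
#' @return A [digraph()].
#' @export
generate_fixture <- function(kind = c("complete", "random", "implanted"),
                             n = 10L, density = 0.2, motif_count = 10L,
                             motif_id = 38, seed = 1L, file = NULL) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (n < 2L) stop("`n` must be at least 2")
  g <- switch(kind,
    complete = {
      pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
      pairs <- pairs[pairs$from != pairs$to, ]
      digraph(as.matrix(pairs), n_nodes = n)
    },
    random = {
      if (density <= 0 || density > 1)
        stop("`density` must be in (0, 1]; a zero-density graph is empty")
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      pick <- matrix(stats::runif(n * n) < density, n, n)
      diag(pick) <- FALSE
      if (!any(pick)) stop("empty graph: no arcs drawn at this density")
      digraph(which(pick, arr.ind = TRUE)[, c(1L, 2L), drop = FALSE], n_nodes = n)
    },
    implanted = {
      if (n < 3L * motif_count)
        stop("`n` must be at least 3 * `motif_count` for disjoint implants")
      base <- generate_fixture("random", n = n, density = density, seed = seed)
      motif <- decode_graph_id(motif_id, 3L)
      arcs <- base$arcs
      for (t in seq_len(motif_count)) {
        triple <- (3L * (t - 1L) + 1L):(3L * t)
        inside <- arcs[, 1L] %in% triple & arcs[, 2L] %in% triple
        arcs <- arcs[!inside, , drop = FALSE]
        arcs <- rbind(arcs, cbind(triple[motif$arcs[, 1L]], triple[motif$arcs[, 2L]]))
      }
      digraph(arcs, n_nodes = n)
    })
  if (!is.null(file)) write_edge_list(g, file)
  g
}
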