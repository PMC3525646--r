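#' Detect network motifs in a digraph
#'
#' The full detection pipeline: (1) census of the input network (always run
#' in serial); (2) generation of `n_comparison` degree-preserving comparison
#' graphs under the chosen null model; (3) census of each comparison graph,
#' restricted to the classes present in the input network (a task per
#' comparison graph, farmed to a worker pool when `threads > 1`); (4) per
#' class, empirical p-value, Z-score and concentration, and the motif call.
#' Because every comparison graph is reproducible from `(seed, index)` alone,
#' the report is identical for any thread count at a fixed seed.
#'
#' @param g the input [digraph()], or a path to an edge-list file
#'   (see [read_edge_list()]).
#' @param k motif size, 3..6.
#' @param method,n_comparison,burnin,switches_per_arc,seed passed to
#'   [null_model_config()].
#' @param threads size of the worker pool for the comparison censuses.
#' @param alpha,min_frequency motif-call thresholds, see [call_motifs()].
#' @param p_add_one use the `(r + 1) / (M + 1)` p-value convention.
#' @return A data.frame of class `"motif_report"`, one row per class found in
#'   the input network, ordered by descending frequency (ties by ascending
#'   ID), with columns `id` (canonical ID for k <= 5, representative ID for
#'   k = 6), `adj` (the k x k 0/1 adjacency string), `frequency`,
#'   `concentration`, `null_mean`, `null_sd`, `z_score` (`NA` when the null
#'   sd is zero), `p_value` and `is_motif`. The per-class, per-comparison
#'   count matrix is attached as `attr(, "null_counts")` (classes x M) and
#'   the run configuration as `attr(, "config")`.
#' @examples
#' g <- generate_fixture("random", n = 15, density = 0.2, seed = 7)
#' rep <- run_detection(g, k = 3, n_comparison = 20, seed = 42)
#' head(rep)
#' @export
run_detection <- function(g, k = 3L,
                          method = c("lc", "f", "nr", "gc", "ulc"),
                          n_comparison = 100L, burnin = 0L,
                          switches_per_arc = 3, threads = 1L, seed = 1L,
                          alpha = 0.05, min_frequency = 0L,
                          p_add_one = FALSE) {
  if (is.character(g)) g <- read_edge_list(g)
  stopifnot(inherits(g, "digraph"))
  k <- as.integer(k)
  if (k < 3L || k > 6L)
    stop("motif detection searches for k-node motifs for 3 <= k <= 6")
  threads <- max(1L, as.integer(threads))
  cfg <- null_model_config(method = method, n_comparison = n_comparison,
                           burnin = burnin, switches_per_arc = switches_per_arc,
                           seed = seed)
  table <- build_canon_table(if (k <= 5L) k else 5L)

  input_cen <- census(g, k, table)
  if (length(input_cen$ids) == 0L)
    stop("the input network contains no connected ", k, "-node subgraphs")

  one_comparison <- function(i) {
    gi <- generate_comparison(g, cfg, i)
    census_against(gi, k, input_cen, table)
  }
  idx <- seq_len(cfg$n_comparison)
  if (threads > 1L && .Platform$OS.type == "unix") {
    counts <- parallel::mclapply(idx, one_comparison, mc.cores = threads)
  } else {
    counts <- lapply(idx, one_comparison)
  }
  null_counts <- do.call(cbind, counts)  # classes x M

  conc <- input_cen$counts / input_cen$total
  report <- data.frame(
    id = input_cen$ids,
    adj = vapply(input_cen$ids, adjacency_string, character(1), k = k),
    frequency = input_cen$counts,
    concentration = conc,
    null_mean = apply(null_counts, 1L, mean),
    null_sd = apply(null_counts, 1L, stats::sd),
    z_score = vapply(seq_along(input_cen$ids), function(r)
      motif_z_score(input_cen$counts[r], null_counts[r, ]), numeric(1)),
    p_value = vapply(seq_along(input_cen$ids), function(r)
      motif_p_value(input_cen$counts[r], null_counts[r, ], add_one = p_add_one),
      numeric(1)),
    stringsAsFactors = FALSE
  )
  report$is_motif <- FALSE
  report <- call_motifs(report, alpha = alpha, min_frequency = min_frequency)

  ord <- order(-report$frequency, report$id)
  report <- report[ord, , drop = FALSE]
  rownames(report) <- NULL
  null_counts <- null_counts[ord, , drop = FALSE]
  rownames(null_counts) <- format(report$id, scientific = FALSE, trim = TRUE)

  attr(report, "null_counts") <- null_counts
  attr(report, "config") <- c(list(k = k, alpha = alpha,
                                   min_frequency = min_frequency,
                                   threads = threads), unclass(cfg))
  attr(report, "total_subgraphs") <- input_cen$total
  class(report) <- c("motif_report", "data.frame")
  report
}

#' @export
print.motif_report <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("motif report: k = %d, %d classes, M = %d comparison graphs (%s)\n",
              cfg$k, nrow(x), cfg$n_comparison, cfg$method))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
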