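#' Empirical motif p-value
#'
#' The proportion of comparison graphs containing at least as many copies of
#' the class as the input network: `mean(null_counts >= f_orig)`. Classes
#' absent from a comparison graph contribute a count of zero. With
#' `add_one = TRUE` the `(r + 1) / (M + 1)` convention is used instead, which
#' counts the input network itself as one member of the ensemble.
#'
#' @param f_orig count of the class in the input network.
#' @param null_counts vector of counts across the M comparison graphs.
#' @param add_one use the `(r + 1) / (M + 1)` convention (default `FALSE`).
#' @return A fraction in `[0, 1]`.
#' @examples
#' motif_p_value(5, c(5, 3, 7, 5)) # 0.75
#' @export
motif_p_value <- function(f_orig, null_counts, add_one = FALSE) {
  if (length(null_counts) < 1L) stop("the comparison ensemble is empty")
  r <- sum(null_counts >= f_orig)
  if (add_one) (r + 1) / (length(null_counts) + 1) else r / length(null_counts)
}

#' Motif Z-score
#'
#' `(f_orig - mean(null_counts)) / sd(null_counts)`, with the sample standard
#' deviation (denominator M - 1). No normality of the null counts is implied;
#' the score is reported for comparison purposes only. When the ensemble is
#' degenerate (sd zero, common in the combinatorial-explosion regime where
#' most classes never occur) or has fewer than two members, the score is
#' undefined and `NA` is returned -- never +/-Inf.
#'
#' @inheritParams motif_p_value
#' @return A numeric scalar, or `NA` when undefined.
#' @examples
#' motif_z_score(14, c(8, 12)) # sqrt(2)
#' @export
motif_z_score <- function(f_orig, null_counts) {
  if (length(null_counts) < 2L) return(NA_real_)
  s <- stats::sd(null_counts)
  if (s == 0) return(NA_real_)
  (f_orig - mean(null_counts)) / s
}

#' Class concentrations of a census
#'
#' The concentration of a class is its count divided by the total number of
#' connected k-node induced subgraphs of the same graph; concentrations sum
#' to 1 over the classes of a census.
#'
#' @param counts a [census()] result.
#' @return Named numeric vector of fractions (names are the class IDs).
#' @export
concentration <- function(counts) {
  stopifnot(inherits(counts, "census_result"))
  if (counts$total <= 0) stop("the census is empty: no connected subgraphs")
  stats::setNames(counts$counts / counts$total,
                  format(counts$ids, scientific = FALSE, trim = TRUE))
}

#' Flag motifs in a report
#'
#' A class is called a motif when its p-value is strictly below `alpha` and
#' its input-network frequency is at least `min_frequency`. Both statistics
#' remain reported regardless of the call, since the choice of statistic can
#' change which subgraphs are declared motifs.
#'
#' @param report a `motif_report` data.frame as produced by [run_detection()].
#' @param alpha significance threshold in (0, 1].
#' @param min_frequency minimum input-network count.
#' @return The report with its `is_motif` column recomputed.
#' @export
call_motifs <- function(report, alpha = 0.05, min_frequency = 0L) {
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]")
  if (min_frequency < 0) stop("`min_frequency` must be non-negative")
  report$is_motif <- report$p_value < alpha & report$frequency >= min_frequency
  report
}
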