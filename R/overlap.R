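#' Fisher's exact test for the overlap of two gene sets
#'
#' Builds the 2x2 contingency table of membership in `set_a` and `set_b`
#' within `universe` and computes the one-sided (enrichment) exact p-value
#' by hypergeometric tail summation, together with the sample odds ratio.
#' When a table cell is zero the Haldane correction (+0.5 to every cell)
#' is applied to the odds ratio and flagged. Fully degenerate tables (a
#' set equal to the universe, or an empty set) are flagged and never
#' significant.
#'
#' @param set_a,set_b character vectors of genes, subsets of `universe`.
#' @param universe character vector: the genes tested in both datasets.
#' @param p_thresh,or_thresh significance criteria (defaults 0.01 and 1).
#' @return An `overlap_result` list: `n_universe`, `n_a`, `n_b`,
#'   `n_overlap`, `odds_ratio`, `p_fisher`, `haldane`, `degenerate`,
#'   `significant`.
#' @export
fisher_overlap <- function(set_a, set_b, universe, p_thresh = 0.01, or_thresh = 1) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("contract error: sets must be subsets of the universe")
  N <- length(universe)
  a <- length(set_a); b <- length(set_b)
  k <- length(intersect(set_a, set_b))
  # table [[k, a-k], [b-k, N-a-b+k]]
  cells <- c(k, a - k, b - k, N - a - b + k)
  p <- stats::phyper(k - 1, a, N - a, b, lower.tail = FALSE)
  degenerate <- a == 0 || b == 0 || a == N || b == N
  haldane <- any(cells == 0) && !degenerate
  or <- if (degenerate) NA_real_
        else if (haldane) ((k + 0.5) * (N - a - b + k + 0.5)) /
                          ((a - k + 0.5) * (b - k + 0.5))
        else (k * (N - a - b + k)) / ((a - k) * (b - k))
  structure(list(n_universe = N, n_a = a, n_b = b, n_overlap = k,
                 odds_ratio = or, p_fisher = p, haldane = haldane,
                 degenerate = degenerate,
                 significant = !degenerate && p < p_thresh && is.finite(or) &&
                   or > or_thresh),
            class = "overlap_result")
}

#' Total replication overlap across cell types
#'
#' Sums per-cell-type overlap counts (cell-type-specific calls are
#' disjoint families) and expresses the total as a rounded percentage of
#' the replication dataset's total significant genes.
#'
#' @param results list of [fisher_overlap()] results, or a numeric vector
#'   of per-cell-type overlap counts.
#' @param total_b total number of significant genes in the replication
#'   dataset (default: sum of `n_b` when `results` are overlap objects).
#' @return list with `total_overlap`, `total_b`, `percent_of_b` (rounded
#'   to the nearest integer) and the per-cell-type counts.
#' @export
summarize_overlap <- function(results, total_b = NULL) {
  if (is.numeric(results)) {
    counts <- results
    if (is.null(total_b)) stop("total_b required when passing raw counts")
  } else {
    counts <- vapply(results, function(r) r$n_overlap, numeric(1))
    if (is.null(total_b)) total_b <- sum(vapply(results, function(r) r$n_b, numeric(1)))
  }
  total <- sum(counts)
  pct <- if (total_b > 0) round(100 * total / total_b) else 0
  list(total_overlap = total, total_b = total_b, percent_of_b = pct,
       per_cell_type = counts)
}
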