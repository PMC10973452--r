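#' Log2 fold change of group means
#'
#' `log2(mean_alt / mean_ref)` per gene, where `ref` is the first and `alt`
#' the second level of `groups` (e.g. control vs AD). Velocities can have
#' negative means, for which the ratio is undefined; the documented rule is:
#' both means strictly positive gives the standard ratio; both strictly
#' negative gives `log2(|mean_alt| / |mean_ref|)` (a magnitude ratio);
#' discordant signs or a zero mean set the `sign_discordant` flag and leave
#' `log2fc` as `NA` — a sign flip in mean velocity is itself a strong
#' dynamic difference, so flagged genes are retained as candidates and
#' treated as exceeding any fold-change threshold downstream.
#'
#' @param values cells x genes matrix (or a per-cell vector) of the metric.
#' @param groups per-cell factor with two levels (reference first).
#' @return data.frame with columns `gene`, `mean_ref`, `mean_alt`,
#'   `log2fc`, `sign_discordant`.
#' @export
group_fold_change <- function(values, groups) {
  values <- as.matrix(values)
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (any(table(groups) == 0)) stop("empty group")
  m_ref <- colMeans(values[groups == levels(groups)[1], , drop = FALSE])
  m_alt <- colMeans(values[groups == levels(groups)[2], , drop = FALSE])
  disc <- (m_ref * m_alt) <= 0
  l2fc <- rep(NA_real_, length(m_ref))
  both_pos <- !disc & m_ref > 0
  both_neg <- !disc & m_ref < 0
  l2fc[both_pos] <- log2(m_alt[both_pos] / m_ref[both_pos])
  l2fc[both_neg] <- log2(abs(m_alt[both_neg]) / abs(m_ref[both_neg]))
  genes <- colnames(values)
  if (is.null(genes)) genes <- paste0("g", seq_along(m_ref))
  data.frame(gene = genes, mean_ref = m_ref, mean_alt = m_alt,
             log2fc = l2fc, sign_discordant = disc,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Wilcoxon rank-sum test with a subject-level permutation null
#'
#' Computes the observed Mann-Whitney U statistic over cells (average-rank
#' tie handling) per gene, then builds the null distribution by randomly
#' reassigning whole subjects to the two groups (group sizes in subjects
#' preserved, each subject's cells carried together) and recomputing U for
#' each permutation. Permuting subjects rather than cells respects the
#' within-subject correlation of cells and avoids the pseudoreplication
#' that makes cell-label permutation anti-conservative.
#'
#' The two-sided empirical p-value uses the add-one estimator
#' `p = (1 + #\{|U* - mu*| >= |U - mu|\}) / (n_perm + 1)` with
#' `mu = n1 n2 / 2` (recomputed per permutation, since subjects carry
#' different cell counts).
#'
#' @param values cells x genes matrix (or per-cell vector) of the metric.
#' @param cell_groups per-cell factor with two levels; U is computed for
#'   the first level.
#' @param subject_of_cell per-cell subject identifiers.
#' @param n_perm number of permutations (default 5000).
#' @param seed integer seed for the permutation draw.
#' @return list with per-gene vectors `u_stat` and `p_emp`, plus `n1`,
#'   `n2` (cells per group) and `n_perm`.
#' @export
wilcoxon_permutation <- function(values, cell_groups, subject_of_cell,
                                 n_perm = 5000, seed = NULL) {
  values <- as.matrix(values)
  groups <- factor(cell_groups)
  if (nlevels(groups) != 2) stop("cell_groups must have exactly two levels")
  if (n_perm < 1) stop("n_perm must be >= 1")
  subj <- as.character(subject_of_cell)
  subj_tab <- unique(data.frame(subject = subj, group = as.character(groups),
                                stringsAsFactors = FALSE))
  if (anyDuplicated(subj_tab$subject))
    stop("group is not constant within subject")
  if (any(table(subj_tab$group) < 2))
    stop("need at least 2 subjects per group")
  if (!is.null(seed)) set.seed(seed)

  n <- nrow(values)
  R <- apply(values, 2, rank)  # average ranks; NA values propagate
  g1 <- groups == levels(groups)[1]
  n1 <- sum(g1); n2 <- n - n1
  u_obs <- colSums(R[g1, , drop = FALSE]) - n1 * (n1 + 1) / 2
  dev_obs <- abs(u_obs - n1 * n2 / 2)

  n_subj <- nrow(subj_tab)
  k1 <- sum(subj_tab$group == levels(groups)[1])
  subj_idx <- match(subj, subj_tab$subject)
  cells_per_subj <- tabulate(subj_idx, n_subj)

  exceed <- numeric(ncol(values))
  done <- 0L
  block <- 500L
  while (done < n_perm) {
    b <- min(block, n_perm - done)
    sub_ind <- matrix(0, n_subj, b)
    for (j in seq_len(b)) {
      repeat {
        pick <- sample.int(n_subj, k1)
        if (sum(cells_per_subj[pick]) > 0 &&
            sum(cells_per_subj[-pick]) > 0) break
        message("permutation left a group empty of cells; resampled")
      }
      sub_ind[pick, j] <- 1
    }
    ind <- sub_ind[subj_idx, , drop = FALSE]          # cells x b
    n1s <- colSums(ind)
    u_perm <- crossprod(R, ind) -                      # genes x b
      matrix(n1s * (n1s + 1) / 2, ncol(values), b, byrow = TRUE)
    mu_perm <- matrix(n1s * (n - n1s) / 2, ncol(values), b, byrow = TRUE)
    exceed <- exceed + rowSums(abs(u_perm - mu_perm) >= dev_obs - 1e-12)
    done <- done + b
  }
  p_emp <- (1 + exceed) / (n_perm + 1)
  p_emp[!is.finite(u_obs)] <- NA_real_
  list(u_stat = unname(u_obs), p_emp = unname(p_emp),
       n1 = n1, n2 = n2, n_perm = n_perm)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values for a vector of (empirical) p-values; thin wrapper over
#' [stats::p.adjust()] with input validation.
#'
#' @param p p-values in (0, 1].
#' @return q-values, same length and order as `p`.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p[!is.na(p)] <= 0 | p[!is.na(p)] > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Filter a differential table to the significant calls
#'
#' Keeps rows with `q < q_thresh` and `|log2fc| > fc_thresh`; rows flagged
#' `sign_discordant` (mean metric changes sign between groups) count as
#' exceeding any fold-change threshold.
#'
#' @param table data.frame with at least columns `q`, `log2fc` and
#'   optionally `sign_discordant`.
#' @param q_thresh FDR threshold (default 0.05).
#' @param fc_thresh absolute log2 fold-change threshold (default 0.25).
#' @return The filtered data.frame.
#' @export
call_significant <- function(table, q_thresh = 0.05, fc_thresh = 0.25) {
  if (nrow(table) == 0) return(table)
  disc <- if ("sign_discordant" %in% names(table)) table$sign_discordant else FALSE
  fc_ok <- disc | (!is.na(table$log2fc) & abs(table$log2fc) > fc_thresh)
  keep <- !is.na(table$q) & table$q < q_thresh & fc_ok
  table[keep, , drop = FALSE]
}

#' Per-cell-type differential test of velocity or expression between groups
#'
#' Assembles the full differential table: per cell type, the subject-level
#' permutation Wilcoxon test ([wilcoxon_permutation()]), group log2 fold
#' changes ([group_fold_change()]) and BH q-values computed within each
#' (cell type x metric) family, with significance calls at the supplied
#' thresholds.
#'
#' @param values cells x genes matrix of the metric (velocity or
#'   log-normalized expression).
#' @param cells per-cell annotation data.frame with columns `cell_type`,
#'   `group` and `subject_id`.
#' @param metric label stored in the output (`"velocity"` or `"expression"`).
#' @param n_perm permutations per test (default 5000).
#' @param seed integer seed.
#' @param q_thresh,fc_thresh significance thresholds (defaults 0.05, 0.25).
#' @param age optional per-cell age covariate; when supplied, each gene is
#'   residualized on age (least squares) before testing.
#' @return A data.frame with columns `gene`, `cell_type`, `metric`,
#'   `log2fc`, `sign_discordant`, `u_stat`, `p_emp`, `q`, `significant`.
#' @export
differential_table <- function(values, cells, metric = c("velocity", "expression"),
                               n_perm = 5000, seed = 1, q_thresh = 0.05,
                               fc_thresh = 0.25, age = NULL) {
  metric <- match.arg(metric)
  values <- as.matrix(values)
  stopifnot(nrow(values) == nrow(cells))
  out <- list()
  for (tp in unique(cells$cell_type)) {
    sel <- cells$cell_type == tp
    v <- values[sel, , drop = FALSE]
    ok <- colSums(!is.finite(v)) == 0
    v <- v[, ok, drop = FALSE]
    if (ncol(v) == 0) next
    grp <- factor(cells$group[sel], levels = unique(cells$group))
    if (!is.null(age)) {
      a <- age[sel]
      v <- apply(v, 2, function(y) stats::lm.fit(cbind(1, a), y)$residuals)
    }
    fc <- group_fold_change(v, grp)
    wt <- wilcoxon_permutation(v, grp, cells$subject_id[sel],
                               n_perm = n_perm, seed = seed)
    q <- fdr_adjust(wt$p_emp)
    df <- data.frame(gene = fc$gene, cell_type = tp, metric = metric,
                     log2fc = fc$log2fc, sign_discordant = fc$sign_discordant,
                     u_stat = wt$u_stat, p_emp = wt$p_emp, q = q,
                     stringsAsFactors = FALSE)
    df$significant <- !is.na(df$q) & df$q < q_thresh &
      (df$sign_discordant | (!is.na(df$log2fc) & abs(df$log2fc) > fc_thresh))
    out[[tp]] <- df
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Correlation of the test statistic with gene length
#'
#' Pearson correlation between per-gene U statistics and gene length (in
#' bases), used to check that differential-velocity calls are not driven by
#' the over-representation of long unspliced transcripts.
#'
#' @param u_stats per-gene U statistics.
#' @param gene_lengths matched gene lengths (> 0).
#' @return list with `correlation`, `p`, and `undefined` (TRUE when either
#'   input is constant, leaving the correlation undefined).
#' @export
length_bias_check <- function(u_stats, gene_lengths) {
  stopifnot(length(u_stats) == length(gene_lengths))
  if (any(gene_lengths <= 0)) stop("gene lengths must be > 0")
  ok <- is.finite(u_stats) & is.finite(gene_lengths)
  if (stats::sd(u_stats[ok]) == 0 || stats::sd(gene_lengths[ok]) == 0) {
    warning("constant input: correlation undefined")
    return(list(correlation = NA_real_, p = NA_real_, undefined = TRUE))
  }
  ct <- stats::cor.test(u_stats[ok], gene_lengths[ok], method = "pearson")
  list(correlation = unname(ct$estimate), p = ct$p.value, undefined = FALSE)
}
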