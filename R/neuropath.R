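#' Subject-mean velocity per cell type
#'
#' For each cell type, averages the velocities of each subject's cells of
#' that type, gene by gene (NaN-aware), giving a subjects x genes matrix
#' per type; the number of contributing cells is recorded. Subjects lacking
#' a cell type get an NaN row with count 0.
#'
#' @param V a [compute_velocity()] object or cells x genes matrix.
#' @param cells per-cell annotation with columns `subject_id`, `cell_type`.
#' @param subjects optional subject ordering (default: order of appearance).
#' @return A named list per cell type, each with `mean` (subjects x genes)
#'   and `n_cells` (per-subject contributing counts).
#' @export
subject_mean_velocity <- function(V, cells, subjects = NULL) {
  M <- if (inherits(V, "velocity_matrix")) V$V else as.matrix(V)
  stopifnot(nrow(M) == nrow(cells))
  if (is.null(subjects)) subjects <- unique(cells$subject_id)
  out <- list()
  for (tp in unique(cells$cell_type)) {
    res <- matrix(NaN, length(subjects), ncol(M),
                  dimnames = list(subjects, colnames(M)))
    ncell <- stats::setNames(integer(length(subjects)), subjects)
    for (s in subjects) {
      sel <- cells$subject_id == s & cells$cell_type == tp
      ncell[s] <- sum(sel)
      if (any(sel))
        res[s, ] <- colMeans(M[sel, , drop = FALSE], na.rm = TRUE)
    }
    out[[tp]] <- list(mean = res, n_cells = ncell)
  }
  out
}

#' Partial Spearman correlation
#'
#' Rank-transforms `x`, `y` and every numeric covariate (average ranks for
#' ties; factor covariates become indicator columns), residualizes the x
#' and y ranks on an intercept plus the covariate ranks by least squares,
#' and returns the Pearson correlation of the residuals with a t-based
#' p-value on `n - 2 - k` degrees of freedom (`k` covariate columns). With
#' no covariates this reduces to the ordinary Spearman correlation; a
#' trait identical to a covariate is residualized to zero correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates optional matrix/data.frame of covariates (columns may
#'   be factors; they are expanded to numeric indicators).
#' @return list with `rho`, `p`, and `n` (complete observations used);
#'   `rho` is NA with a `reason` when fewer than `k + 3` complete cases.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  Z <- NULL
  if (!is.null(covariates)) {
    Z <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
    if (nrow(Z) != length(x)) stop("covariates must match x in length")
  }
  cc <- is.finite(x) & is.finite(y)
  if (!is.null(Z)) cc <- cc & apply(Z, 1, function(r) all(is.finite(r)))
  k <- if (is.null(Z)) 0 else ncol(Z)
  n <- sum(cc)
  if (n < k + 3)
    return(list(rho = NA_real_, p = NA_real_, n = n,
                reason = "insufficient complete observations"))
  rx <- rank(x[cc]); ry <- rank(y[cc])
  if (!is.null(Z)) {
    D <- cbind(1, apply(Z[cc, , drop = FALSE], 2, rank))
    rx <- stats::lm.fit(D, rx)$residuals
    ry <- stats::lm.fit(D, ry)$residuals
  } else {
    rx <- rx - mean(rx); ry <- ry - mean(ry)
  }
  # a variable fully explained by the covariates leaves only numerical
  # residue; its partial correlation is zero by convention
  scale0 <- sum((rank(x[cc]) - (n + 1) / 2)^2)
  tiny <- 1e-16 * scale0
  if (sum(rx^2) <= tiny || sum(ry^2) <= tiny)
    return(list(rho = 0, p = 1, n = n, reason = "residualized to zero"))
  den <- sqrt(sum(rx^2) * sum(ry^2))
  if (den == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, reason = "constant ranks"))
  rho <- sum(rx * ry) / den
  df <- n - 2 - k
  tval <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = 2 * stats::pt(-abs(tval), df), n = n)
}

#' Associate subject-mean velocities with neuropathology traits
#'
#' For every (cell type, trait) family, computes the covariate-adjusted
#' partial Spearman correlation between each gene's subject-mean velocity
#' and the trait, applies Holm step-down FWER adjustment within the family,
#' and flags genes with adjusted p below `alpha`. Cross-trait overlap of
#' significant genes is summarised per cell type.
#'
#' @param sgm result of [subject_mean_velocity()].
#' @param meta subject metadata with `subject_id`, the trait columns and
#'   the covariate columns.
#' @param traits trait column names (default the four neuropathology
#'   measures np, nft, amyloid, tangles).
#' @param covariates covariate column names (default age, sex, education,
#'   pmi; use `c("age", "sex", "pmi")` for the education-free variant).
#' @param alpha FWER significance level (default 0.001).
#' @param group optional group label: restrict to subjects of that group
#'   (e.g. the pathology group only).
#' @return list with `table` (gene, cell_type, trait, rho, p, p_fwer,
#'   significant) and `overlap` (per cell type, the pairwise overlap
#'   fraction of significant gene sets across traits).
#' @export
trait_association <- function(sgm, meta, traits = c("np", "nft", "amyloid", "tangles"),
                              covariates = c("age", "sex", "education", "pmi"),
                              alpha = 0.001, group = NULL) {
  if (!is.null(group)) meta <- meta[meta$group %in% group, , drop = FALSE]
  if (nrow(meta) < 8) stop("need at least 8 subjects with traits and covariates")
  rows <- list()
  for (tp in names(sgm)) {
    M <- sgm[[tp]]$mean[meta$subject_id, , drop = FALSE]
    for (tr in traits) {
      y <- meta[[tr]]
      if (is.null(y) || stats::sd(y, na.rm = TRUE) %in% c(0, NA)) {
        warning("trait ", tr, " constant or absent: family skipped")
        next
      }
      Z <- meta[, covariates, drop = FALSE]
      res <- lapply(seq_len(ncol(M)), function(g) partial_spearman(M[, g], y, Z))
      p <- vapply(res, `[[`, numeric(1), "p")
      rows[[paste(tp, tr)]] <- data.frame(
        gene = colnames(M), cell_type = tp, trait = tr,
        rho = vapply(res, `[[`, numeric(1), "rho"), p = p,
        p_fwer = stats::p.adjust(p, method = "holm"),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$significant <- !is.na(tab$p_fwer) & tab$p_fwer < alpha

  overlap <- list()
  for (tp in unique(tab$cell_type)) {
    sets <- lapply(split(tab[tab$cell_type == tp & tab$significant, "gene"],
                         tab[tab$cell_type == tp & tab$significant, "trait"]),
                   unique)
    if (length(sets) >= 2) {
      prs <- utils::combn(names(sets), 2)
      frac <- apply(prs, 2, function(pr) {
        u <- union(sets[[pr[1]]], sets[[pr[2]]])
        if (length(u) == 0) 0 else
          length(intersect(sets[[pr[1]]], sets[[pr[2]]])) / length(u)
      })
      overlap[[tp]] <- data.frame(trait_a = prs[1, ], trait_b = prs[2, ],
                                  overlap_fraction = frac)
    }
  }
  list(table = tab, overlap = overlap, alpha = alpha, covariates = covariates)
}
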