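#' Fit the steady-state ratio gamma/beta per gene
#'
#' Estimates, for every gene, the slope of the steady-state line
#' `u = (gamma/beta) s` from the kNN-smoothed moments, using cells in the
#' extreme quantiles of `Ms` (the presumed transcriptional equilibria) and
#' a least-squares fit constrained through the origin.
#'
#' Two estimators are available:
#' \describe{
#'   \item{steady_state}{ordinary least squares of `Mu` on `Ms` through the
#'     origin on the extreme-quantile cells.}
#'   \item{stochastic}{augments the first-moment relation with the
#'     second-moment equation of the counting process,
#'     `2 E[us] + E[u] = gamma' (2 E[s^2] - E[s])`, stacking per-cell
#'     responses `[Mu; 2 Mus + Mu]` against regressors
#'     `[Ms; 2 Mss - Ms]` on the same cells and solving by weighted least
#'     squares through the origin, each equation block weighted by the
#'     inverse of its response variance so the blocks contribute equal
#'     total variance.}
#' }
#'
#' @param moments a [neighbor_moments()] object.
#' @param mode `"steady_state"` or `"stochastic"`.
#' @param quantile_pair lower/upper quantiles of `Ms` delimiting the
#'   extreme cells (default `c(0.05, 0.95)`).
#' @return A `gamma_fit` list with per-gene vectors `gamma`, `r2`, logical
#'   `valid`, character `reason` for invalid genes, and the `mode`.
#' @export
fit_gamma <- function(moments, mode = c("stochastic", "steady_state"),
                      quantile_pair = c(0.05, 0.95)) {
  mode <- match.arg(mode)
  q_lo <- quantile_pair[1]; q_hi <- quantile_pair[2]
  if (!(q_lo > 0 && q_lo < q_hi && q_hi < 1))
    stop("quantile_pair must satisfy 0 < q_lo < q_hi < 1")
  Mu <- moments$Mu; Ms <- moments$Ms
  G <- ncol(Ms)
  gamma <- r2 <- rep(NA_real_, G)
  valid <- rep(FALSE, G)
  reason <- rep(NA_character_, G)
  for (g in seq_len(G)) {
    ms <- Ms[, g]; mu <- Mu[, g]
    if (all(ms == 0)) { reason[g] <- "all-zero Ms"; next }
    qq <- stats::quantile(ms, c(q_lo, q_hi), names = FALSE)
    sel <- ms <= qq[1] | ms >= qq[2]
    x <- ms[sel]; y <- mu[sel]
    if (mode == "stochastic") {
      y2 <- 2 * moments$Mus[sel, g] + y
      x2 <- 2 * moments$Mss[sel, g] - x
      v1 <- stats::var(y); v2 <- stats::var(y2)
      w1 <- if (is.finite(v1) && v1 > 0) 1 / v1 else 1
      w2 <- if (is.finite(v2) && v2 > 0) 1 / v2 else 1
      w <- c(rep(w1, length(y)), rep(w2, length(y2)))
      x <- c(x, x2); y <- c(y, y2)
    } else w <- rep(1, length(x))
    sxx <- sum(w * x * x)
    if (sxx == 0) { reason[g] <- "degenerate regressors"; next }
    slope <- sum(w * x * y) / sxx
    if (!is.finite(slope)) { reason[g] <- "non-finite slope"; next }
    if (slope <= 0) { gamma[g] <- slope; reason[g] <- "non-positive slope"; next }
    gamma[g] <- slope
    valid[g] <- TRUE
    ss_tot <- sum(w * y^2)
    r2[g] <- if (ss_tot > 0) 1 - sum(w * (y - slope * x)^2) / ss_tot else NA_real_
  }
  structure(list(gamma = gamma, r2 = r2, valid = valid, reason = reason,
                 mode = mode, quantile_pair = quantile_pair,
                 genes = colnames(Ms)),
            class = "gamma_fit")
}

#' Per-cell, per-gene RNA velocity as the residual from the steady-state line
#'
#' `V[c, g] = Mu[c, g] - gamma_g * Ms[c, g]`: the deviation of the observed
#' (smoothed) unspliced abundance from the level expected at transcriptional
#' equilibrium. Positive values indicate upregulation (induction), negative
#' values downregulation (repression). Genes with an invalid fit are
#' NaN-masked, never silently zeroed.
#'
#' @param moments a [neighbor_moments()] object.
#' @param fit a [fit_gamma()] object on the same genes.
#' @return A `velocity_matrix` list with the cells x genes matrix `V` and
#'   the per-gene `valid` flags.
#' @export
compute_velocity <- function(moments, fit) {
  if (!inherits(fit, "gamma_fit")) stop("fit must be a gamma_fit object")
  if (ncol(moments$Ms) != length(fit$gamma))
    stop("contract error: moments and fit disagree on the number of genes")
  if (!is.null(fit$genes) && !is.null(colnames(moments$Ms)) &&
      !identical(fit$genes, colnames(moments$Ms)))
    stop("contract error: moments and fit disagree on gene identity")
  gam <- fit$gamma
  gam[!fit$valid] <- NA_real_
  V <- moments$Mu - sweep(moments$Ms, 2, gam, `*`)
  V[, !fit$valid] <- NaN
  structure(list(V = V, valid = fit$valid, genes = fit$genes,
                 barcodes = rownames(moments$Ms)),
            class = "velocity_matrix")
}

# Welch's t for each column of `values`, group `in_type` vs the rest.
# Variance floor keeps zero-variance constructed signals finite.
.welch_t <- function(values, in_type) {
  x <- values[in_type, , drop = FALSE]
  y <- values[!in_type, , drop = FALSE]
  n1 <- nrow(x); n2 <- nrow(y)
  m1 <- colMeans(x); m2 <- colMeans(y)
  v1 <- apply(x, 2, stats::var); v2 <- apply(y, 2, stats::var)
  se2 <- pmax(v1 / n1 + v2 / n2, .Machine$double.eps)
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / pmax((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1),
                     .Machine$double.xmin)
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, p = p, df = df)
}

#' Rank genes driving cell-type-specific velocity dynamics
#'
#' For every cell type, a differential-velocity Welch's t-test of each
#' gene's velocity in the cells of that type against all other cells; genes
#' are ranked by the t statistic in decreasing order, so the top genes are
#' those whose upregulation is most specific to the type.
#'
#' @param V a [compute_velocity()] object (or a plain cells x genes matrix).
#' @param cell_types per-cell type labels (at least 2 types, each with at
#'   least 2 cells).
#' @return A data.frame with columns `cell_type`, `gene`, `t`, `p`, `rank`,
#'   ordered by decreasing `t` within each cell type; NaN-masked genes are
#'   omitted.
#' @export
rank_velocity_genes <- function(V, cell_types) {
  M <- if (inherits(V, "velocity_matrix")) V$V else as.matrix(V)
  types <- unique(cell_types)
  if (length(types) < 2) stop("need at least 2 cell types for a contrast")
  if (any(table(cell_types) < 2)) stop("every cell type needs at least 2 cells")
  ok <- colSums(!is.finite(M)) == 0
  M <- M[, ok, drop = FALSE]
  genes <- colnames(M)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(M)))
  out <- lapply(types, function(tp) {
    w <- .welch_t(M, cell_types == tp)
    df <- data.frame(cell_type = tp, gene = genes, t = w$t, p = w$p,
                     stringsAsFactors = FALSE, row.names = NULL)
    df <- df[order(-df$t), , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    df
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
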