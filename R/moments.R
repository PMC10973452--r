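# blocked exact Euclidean kNN (self included); returns n x k index matrix.
# Block-wise cross-products keep memory at O(block * n).
.knn_index <- function(X, k, block = 512L) {
  n <- nrow(X)
  stopifnot(k >= 1, k <= n)
  xsq <- rowSums(X^2)
  out <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(xsq[idx], xsq, "+") - 2 * tcrossprod(X[idx, , drop = FALSE], X)
    for (r in seq_along(idx)) {
      dv <- d2[r, ]
      if (k < n) {
        thr <- sort.int(dv, partial = k)[k]
        cand <- which(dv <= thr)
        if (length(cand) > k) cand <- cand[order(dv[cand])][seq_len(k)]
      } else cand <- order(dv)
      out[idx[r], ] <- cand
    }
  }
  out
}

#' kNN-smoothed first and second moments of the normalized layers
#'
#' Principal components are computed on log(1 + S) of the size-normalized
#' spliced layer; cells are connected to their `k` nearest neighbours
#' (Euclidean distance in PC space, self included) and the moments are
#' neighbour averages:
#' `Mu` and `Ms` of the normalized unspliced/spliced values, `Mss` of
#' `S^2` and `Mus` of `U*S`. These smoothed moments are the inputs of the
#' steady-state and stochastic velocity estimators.
#'
#' @param S_norm,U_norm cells x genes size-normalized layers (dense), as
#'   produced by [normalize_counts()] in `velocity_layers` mode.
#' @param n_pcs number of principal components (default 30, reduced when
#'   the data are smaller).
#' @param k number of nearest neighbours including self (default 100;
#'   reduced to `cells - 1` with a warning when fewer cells are available).
#' @param by optional per-cell grouping (e.g. subject identifiers). When
#'   supplied, neighbours are restricted to cells of the same group
#'   (per-subject pooling): smoothing then never crosses subjects, which
#'   keeps downstream subject-level permutation tests exactly valid even
#'   when the pooled neighbour graph would separate the clinical groups.
#'   The default (`NULL`) pools all cells into one graph.
#' @return A `moments` list with matrices `Mu`, `Ms`, `Mss`, `Mus`, the
#'   neighbour index matrix `nn` (ragged rows padded with the cell's own
#'   index when `by` groups are smaller than `k`), and the PC scores `pcs`.
#' @export
neighbor_moments <- function(S_norm, U_norm, n_pcs = 30, k = 100, by = NULL) {
  S_norm <- as.matrix(S_norm); U_norm <- as.matrix(U_norm)
  stopifnot(all(dim(S_norm) == dim(U_norm)))
  n <- nrow(S_norm)
  if (n < 2) stop("need at least 2 cells")
  if (k >= n) {
    warning("k = ", k, " >= number of cells; reduced to ", n - 1)
    k <- n - 1
  }
  n_pcs <- min(n_pcs, n - 1, ncol(S_norm))
  pcs <- stats::prcomp(log1p(S_norm), rank. = n_pcs, center = TRUE,
                       scale. = FALSE)$x
  if (is.null(by)) {
    nn <- .knn_index(pcs, k)
    A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                              j = as.vector(t(nn)),
                              x = 1 / k, dims = c(n, n))
  } else {
    stopifnot(length(by) == n)
    nn <- matrix(rep(seq_len(n), k), n, k)  # pad with self
    ii <- jj <- xx <- vector("list", length(unique(by)))
    parts <- split(seq_len(n), by)
    for (p in seq_along(parts)) {
      idx <- parts[[p]]
      kp <- min(k, length(idx))
      nnp <- if (length(idx) == 1) matrix(1L, 1, 1)
             else .knn_index(pcs[idx, , drop = FALSE], kp)
      nn[idx, seq_len(kp)] <- matrix(idx[nnp], nrow(nnp), ncol(nnp))
      ii[[p]] <- rep(idx, each = kp)
      jj[[p]] <- as.vector(t(matrix(idx[nnp], nrow(nnp), ncol(nnp))))
      xx[[p]] <- rep(1 / kp, length(idx) * kp)
    }
    A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                              dims = c(n, n))
  }
  structure(list(
    Mu = as.matrix(A %*% U_norm),
    Ms = as.matrix(A %*% S_norm),
    Mss = as.matrix(A %*% (S_norm^2)),
    Mus = as.matrix(A %*% (U_norm * S_norm)),
    nn = nn, pcs = pcs, k = k, n_pcs = n_pcs, by = by
  ), class = "moments")
}
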