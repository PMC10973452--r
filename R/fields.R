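#' Per-cell speed: the length of the velocity vector
#'
#' Euclidean norm of each cell's velocity across all valid genes; NaN-masked
#' genes are excluded per cell. A whole-transcriptome scalar summary of how
#' fast a cell's expression state is changing.
#'
#' @param V a [compute_velocity()] object or cells x genes matrix.
#' @return Non-negative per-cell speeds; NaN (with a message) for cells
#'   with no valid genes.
#' @export
cell_speed <- function(V) {
  M <- if (inherits(V, "velocity_matrix")) V$V else as.matrix(V)
  fin <- is.finite(M)
  M[!fin] <- 0
  sp <- sqrt(rowSums(M^2))
  none <- rowSums(fin) == 0
  if (any(none)) {
    message(sum(none), " cell(s) with no valid genes: speed set to NaN")
    sp[none] <- NaN
  }
  sp
}

#' Compare cell speeds between two groups
#'
#' Group medians and a two-sided Wilcoxon rank-sum p-value over cells.
#'
#' @param speeds per-cell speeds.
#' @param groups per-cell factor with two levels.
#' @return list with `median_a`, `median_b` (first/second level) and
#'   `wilcoxon_p`.
#' @export
compare_speed <- function(speeds, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  a <- speeds[groups == levels(groups)[1]]
  b <- speeds[groups == levels(groups)[2]]
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("both groups need at least 2 cells")
  list(median_a = stats::median(a), median_b = stats::median(b),
       wilcoxon_p = stats::wilcox.test(a, b, exact = FALSE)$p.value)
}

# cosine similarities between velocity v and displacement rows of D
.cosine <- function(v, D) {
  nv <- sqrt(sum(v^2))
  nd <- sqrt(rowSums(D^2))
  num <- as.vector(D %*% v)
  cs <- num / (nv * nd)
  cs[!is.finite(cs)] <- 0
  cs
}

#' Project gene-space velocities onto a 2D embedding
#'
#' For each cell, the cosine similarity between its velocity vector and the
#' gene-space displacement to each of its neighbours is turned into softmax
#' transition weights (temperature set adaptively to the cell's median
#' absolute cosine similarity); the projected vector is the weighted mean
#' of unit embedding displacements to the neighbours, minus their uniform
#' mean (baseline correction), so a zero or uninformative velocity maps to
#' the zero vector.
#'
#' @param V a [compute_velocity()] object or cells x genes matrix.
#' @param expression cells x genes gene-space positions used for
#'   displacements (typically the smoothed spliced moments `Ms`).
#' @param coords cells x 2 embedding coordinates (external t-SNE/UMAP or a
#'   PCA-2D fallback).
#' @param neighbors cells x k neighbour index matrix (e.g. `moments$nn`);
#'   self-indices are ignored.
#' @param sigma optional fixed softmax temperature (default adaptive).
#' @return An `embedded_velocity` list with `coords` and the cells x 2
#'   projected vectors `vec2d`.
#' @export
embed_velocity <- function(V, expression, coords, neighbors, sigma = NULL) {
  M <- if (inherits(V, "velocity_matrix")) V$V else as.matrix(V)
  X <- as.matrix(expression)
  coords <- as.matrix(coords)
  stopifnot(nrow(M) == nrow(X), nrow(M) == nrow(coords), ncol(coords) == 2)
  ok <- colSums(!is.finite(M)) == 0
  M <- M[, ok, drop = FALSE]
  X <- X[, ok, drop = FALSE]
  n <- nrow(M)
  vec2d <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    nb <- setdiff(neighbors[i, ], i)
    if (length(nb) == 0) { message("isolated cell ", i, ": zero vector"); next }
    v <- M[i, ]
    E <- coords[nb, , drop = FALSE] -
      matrix(coords[i, ], length(nb), 2, byrow = TRUE)
    en <- sqrt(rowSums(E^2))
    keep <- en > 0
    if (!any(keep)) next
    E <- E[keep, , drop = FALSE] / en[keep]
    if (sum(v^2) == 0) next  # uniform weights cancel against the baseline
    D <- X[nb[keep], , drop = FALSE] - matrix(X[i, ], sum(keep), ncol(X), byrow = TRUE)
    cs <- .cosine(v, D)
    sg <- if (is.null(sigma)) stats::median(abs(cs)) else sigma
    if (!is.finite(sg) || sg <= 0) sg <- 1
    w <- exp((cs - max(cs)) / sg)
    w <- w / sum(w)
    vec2d[i, ] <- colSums(w * E) - colMeans(E)
  }
  structure(list(coords = coords, vec2d = vec2d), class = "embedded_velocity")
}

# Gaussian-kernel smoothing of vectors onto grid points; coverage where the
# accumulated weight reaches that of a single cell two bandwidths away.
.smooth_field <- function(coords, vec, grid, h) {
  d2 <- outer(rowSums(grid^2), rowSums(coords^2), "+") -
    2 * tcrossprod(grid, coords)
  W <- exp(-pmax(d2, 0) / (2 * h^2))
  tot <- rowSums(W)
  fld <- (W %*% vec) / tot
  fld[tot == 0, ] <- NA_real_
  list(field = as.matrix(fld), covered = tot >= exp(-2))
}

# fill uncovered grid nodes by iterative averaging of adjacent covered nodes
# (discrete harmonic interpolation on the lattice)
.fill_lattice <- function(field, covered, nx, ny, target) {
  need <- target & !covered
  while (any(need)) {
    progressed <- FALSE
    for (p in which(need)) {
      ix <- (p - 1) %% nx + 1
      iy <- (p - 1) %/% nx + 1
      nbr <- c(if (ix > 1) p - 1, if (ix < nx) p + 1,
               if (iy > 1) p - nx, if (iy < ny) p + nx)
      nbr <- nbr[covered[nbr]]
      if (length(nbr) > 0) {
        field[p, ] <- colMeans(field[nbr, , drop = FALSE])
        covered[p] <- TRUE
        need[p] <- FALSE
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  list(field = field, covered = covered)
}

#' Residual velocity field between two groups on a shared lattice
#'
#' Each group's projected velocity vectors are smoothed onto a common
#' regular lattice spanning the joint embedding support (Gaussian kernel,
#' bandwidth defaulting to the lattice spacing). Lattice nodes covered by
#' only one group are filled for the other group by interpolation from its
#' covered neighbours, so both fields are defined at identical coordinates.
#' The residual is the difference of the two fields; z-scores are computed
#' over lattice nodes from the residual norms, and the mask flags nodes
#' with `|z|` beyond the threshold. Field directions carry no intrinsic
#' biological meaning; only the masked z-magnitudes are interpreted.
#'
#' @param emb_a,emb_b [embed_velocity()] results for the two groups, on a
#'   common coordinate system.
#' @param grid_size lattice nodes per axis (default 50).
#' @param bandwidth Gaussian kernel bandwidth (default: mean lattice
#'   spacing).
#' @param z_thresh z-score threshold for the mask (default 1.96).
#' @return A `field_grid` list: `grid_coords` (G x 2), `field_a`,
#'   `field_b`, `residual` (G x 2), `z`, logical `mask` and `defined`.
#' @export
residual_field <- function(emb_a, emb_b, grid_size = 50, bandwidth = NULL,
                           z_thresh = 1.96) {
  ca <- emb_a$coords; cb <- emb_b$coords
  lo <- pmin(apply(ca, 2, min), apply(cb, 2, min))
  hi <- pmax(apply(ca, 2, max), apply(cb, 2, max))
  if (any(hi <= lo)) stop("degenerate embedding support")
  gx <- seq(lo[1], hi[1], length.out = grid_size)
  gy <- seq(lo[2], hi[2], length.out = grid_size)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  h <- if (is.null(bandwidth)) mean(c(diff(gx)[1], diff(gy)[1])) else bandwidth

  fa <- .smooth_field(ca, emb_a$vec2d, grid, h)
  fb <- .smooth_field(cb, emb_b$vec2d, grid, h)
  if (!any(fa$covered & fb$covered))
    stop("empty overlap of embedding supports")
  fa_f <- .fill_lattice(fa$field, fa$covered, grid_size, grid_size, fb$covered)
  fb_f <- .fill_lattice(fb$field, fb$covered, grid_size, grid_size, fa$covered)
  defined <- fa_f$covered & fb_f$covered

  residual <- fa_f$field - fb_f$field
  residual[!defined, ] <- NA_real_
  nrm <- sqrt(rowSums(residual^2))
  mu <- mean(nrm[defined]); sdv <- stats::sd(nrm[defined])
  z <- rep(NA_real_, nrow(grid))
  z[defined] <- if (is.finite(sdv) && sdv > 0) (nrm[defined] - mu) / sdv else 0
  mask <- !is.na(z) & abs(z) > z_thresh
  structure(list(grid_coords = grid, field_a = fa_f$field, field_b = fb_f$field,
                 residual = residual, z = z, mask = mask, defined = defined,
                 bandwidth = h, z_thresh = z_thresh),
            class = "field_grid")
}
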