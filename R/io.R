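#' Paired spliced/unspliced count layers
#'
#' Container for the two cells x genes count matrices proxying mature
#' (spliced, exonic) and nascent (unspliced, intronic) mRNA. Both layers
#' share shape, barcode order and feature order.
#'
#' @param S,U cells x genes non-negative count matrices (dense or sparse).
#' @param barcodes character vector of cell identifiers (no duplicates).
#' @param features data.frame with at least an `id` column; `symbol` and
#'   `length` (bases) are optional.
#' @return A `count_layers` list.
#' @export
count_layers <- function(S, U, barcodes, features) {
  if (is.character(features)) features <- data.frame(id = features, stringsAsFactors = FALSE)
  if (!all(dim(S) == dim(U)))
    stop("format error: S and U layers differ in shape")
  if (nrow(S) != length(barcodes))
    stop("format error: barcode list length (", length(barcodes),
         ") does not match matrix rows (", nrow(S), ")")
  if (ncol(S) != nrow(features))
    stop("format error: feature list length (", nrow(features),
         ") does not match matrix columns (", ncol(S), ")")
  if (anyDuplicated(barcodes))
    stop("format error: duplicate barcodes")
  if (min(S) < 0 || min(U) < 0)
    stop("format error: negative counts")
  rownames(S) <- rownames(U) <- barcodes
  colnames(S) <- colnames(U) <- features$id
  structure(list(S = S, U = U, barcodes = barcodes, features = features),
            class = "count_layers")
}

#' @export
dim.count_layers <- function(x) dim(x$S)

.read_mtx <- function(path) {
  header <- readLines(path, n = 1)
  if (!grepl("^%%MatrixMarket matrix coordinate", header))
    stop("format error in ", path, ": malformed MatrixMarket header")
  m <- Matrix::readMM(path)
  methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
}

#' Read spliced/unspliced count layers from a directory
#'
#' Expects the file layout written by [write_dataset()]: `spliced.mtx`,
#' `unspliced.mtx` (Matrix-Market coordinate, 1-based indices),
#' `barcodes.tsv` (one barcode per line) and `features.tsv` (tab-separated
#' with header). Shapes are validated against the barcode and feature lists.
#'
#' @param directory directory containing the files.
#' @param spliced,unspliced,barcodes,features alternative file names.
#' @return A [count_layers()] object.
#' @export
read_matrices <- function(directory, spliced = "spliced.mtx",
                          unspliced = "unspliced.mtx",
                          barcodes = "barcodes.tsv", features = "features.tsv") {
  fp <- function(x) {
    p <- file.path(directory, x)
    if (!file.exists(p)) stop("file-system error: missing ", p)
    p
  }
  S <- .read_mtx(fp(spliced))
  U <- .read_mtx(fp(unspliced))
  bc <- readLines(fp(barcodes))
  ft <- utils::read.table(fp(features), sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (nrow(S) != length(bc))
    stop("format error in ", spliced, ": ", nrow(S), " rows but ",
         length(bc), " barcodes")
  count_layers(S = S, U = U, barcodes = bc, features = ft)
}

#' Restrict count layers and annotation to shared cells and a gene list
#'
#' Subsets both layers and the cell annotation to the intersection of
#' barcodes, and the genes to `keep_genes` (order preserved). Cells whose
#' annotated type is in `exclude_types` (e.g. endothelial cells and
#' pericytes, typically dropped for very low counts) are removed.
#'
#' @param counts a [count_layers()] object.
#' @param cells data.frame with columns barcode, subject_id, cell_type, group.
#' @param keep_genes character vector of feature ids to retain, in the
#'   desired order; `NULL` keeps all features.
#' @param exclude_types character vector of cell types to drop (default none).
#' @return A list with elements `counts` and `cells`.
#' @export
harmonize <- function(counts, cells, keep_genes = NULL, exclude_types = character()) {
  if (!inherits(counts, "count_layers")) stop("counts must be a count_layers object")
  if (anyDuplicated(cells$barcode)) stop("format error: duplicate barcodes in annotation")
  keep_cells <- intersect(counts$barcodes, cells$barcode)
  ann <- cells[match(keep_cells, cells$barcode), , drop = FALSE]
  if (length(exclude_types) > 0) {
    ok <- !(ann$cell_type %in% exclude_types)
    ann <- ann[ok, , drop = FALSE]
    keep_cells <- keep_cells[ok]
  }
  if (is.null(keep_genes)) keep_genes <- counts$features$id
  gi <- match(keep_genes, counts$features$id)
  gi <- gi[!is.na(gi)]
  if (length(keep_cells) == 0 || length(gi) == 0)
    stop("empty result: no shared cells or genes after harmonization")
  ci <- match(keep_cells, counts$barcodes)
  out <- count_layers(S = counts$S[ci, gi, drop = FALSE],
                      U = counts$U[ci, gi, drop = FALSE],
                      barcodes = keep_cells,
                      features = counts$features[gi, , drop = FALSE])
  rownames(ann) <- NULL
  list(counts = out, cells = ann)
}

#' Normalize count layers for velocity estimation or expression analysis
#'
#' Two modes mirror the two downstream analyses:
#' \describe{
#'   \item{velocity_layers}{each cell's spliced row and unspliced row are
#'     divided by that cell's within-layer total and rescaled by the median
#'     of the layer totals, so both layers are size-normalized onto a
#'     common count scale.}
#'   \item{expression}{spliced counts divided by the per-cell total,
#'     multiplied by 10,000 and transformed with log(1 + x) (natural log).}
#' }
#' Cells with a zero total in any required layer are excluded with a
#' warning and reported in the `dropped` attribute.
#'
#' @param counts a [count_layers()] object.
#' @param mode `"velocity_layers"` or `"expression"`.
#' @return For `velocity_layers`, a list with dense matrices `S`, `U`,
#'   `barcodes`, `features` and `dropped`; for `expression`, a dense
#'   log-normalized matrix with a `dropped` attribute.
#' @export
normalize_counts <- function(counts, mode = c("velocity_layers", "expression")) {
  mode <- match.arg(mode)
  S <- as.matrix(counts$S)
  rs_s <- rowSums(S)
  if (mode == "expression") {
    keep <- rs_s > 0
    if (!all(keep))
      warning(sum(!keep), " cell(s) with zero spliced total excluded: ",
              paste(utils::head(counts$barcodes[!keep], 5), collapse = ", "))
    E <- log1p(S[keep, , drop = FALSE] / rs_s[keep] * 1e4)
    rownames(E) <- counts$barcodes[keep]
    attr(E, "dropped") <- counts$barcodes[!keep]
    return(E)
  }
  U <- as.matrix(counts$U)
  rs_u <- rowSums(U)
  keep <- rs_s > 0 & rs_u > 0
  if (!all(keep))
    warning(sum(!keep), " cell(s) with a zero layer total excluded: ",
            paste(utils::head(counts$barcodes[!keep], 5), collapse = ", "))
  Sn <- S[keep, , drop = FALSE] / rs_s[keep] * stats::median(rs_s[keep])
  Un <- U[keep, , drop = FALSE] / rs_u[keep] * stats::median(rs_u[keep])
  list(S = Sn, U = Un, barcodes = counts$barcodes[keep],
       features = counts$features, dropped = counts$barcodes[!keep])
}
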