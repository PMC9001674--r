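#' Construct a genes-by-cells count matrix with metadata
#'
#' Lightweight container binding a raw count matrix (genes in rows, cells in
#' columns) to per-gene and per-cell annotations.  Gene annotations carry a
#' logical mitochondrial flag used by quality control; cell annotations carry
#' at minimum a unique `cell_id` and typically `birthdate`, `stage`, an
#' optional recorded `radial_position` in `[0, 1]` and, for simulated data,
#' the ground-truth subtype label.
#'
#' @param counts Integer matrix (base or `Matrix` sparse), genes x cells,
#'   non-negative.  Row names are gene identifiers, column names cell ids.
#' @param gene_meta `data.frame` with columns `gene_id` and logical `mito`;
#'   one row per matrix row.  If `NULL`, built from row names with the mito
#'   flag inferred from the `"mt-"` name prefix.
#' @param cell_meta `data.frame` with a `cell_id` column; one row per matrix
#'   column.  If `NULL`, built from column names.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_meta = NULL, cell_meta = NULL) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("cell%05d", seq_len(ncol(counts)))
  if (is.null(gene_meta)) {
    gene_meta <- data.frame(
      gene_id = rownames(counts),
      mito = startsWith(rownames(counts), "mt-"),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(cell_id = colnames(counts), stringsAsFactors = FALSE)
  }
  x <- structure(
    list(counts = counts, gene_meta = gene_meta, cell_meta = cell_meta),
    class = "count_matrix"
  )
  validate_count_matrix(x)
}

validate_count_matrix <- function(x) {
  counts <- x$counts
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  vals <- if (inherits(counts, "sparseMatrix")) counts@x else as.vector(counts)
  if (length(vals) && any(vals != floor(vals)))
    stop("counts must be integers", call. = FALSE)
  if (anyDuplicated(x$gene_meta$gene_id)) stop("gene ids must be unique", call. = FALSE)
  if (anyDuplicated(x$cell_meta$cell_id)) stop("cell ids must be unique", call. = FALSE)
  if (nrow(x$gene_meta) != nrow(counts) ||
      (nrow(counts) > 0 &&
       !identical(as.character(x$gene_meta$gene_id), rownames(counts))))
    stop("gene_meta rows must align with count matrix rows", call. = FALSE)
  if (nrow(x$cell_meta) != ncol(counts) ||
      (ncol(counts) > 0 &&
       !identical(as.character(x$cell_meta$cell_id), colnames(counts))))
    stop("cell_meta rows must align with count matrix columns", call. = FALSE)
  if (!is.logical(x$gene_meta$mito))
    stop("gene_meta$mito must be logical", call. = FALSE)
  x
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d cells (%d mitochondrial genes)\n",
              nrow(x$counts), ncol(x$counts), sum(x$gene_meta$mito)))
  extra <- setdiff(names(x$cell_meta), "cell_id")
  if (length(extra)) cat("cell metadata:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by gene and/or cell index
#'
#' @param x A `count_matrix`.
#' @param genes,cells Index vectors (integer, logical or character ids);
#'   `NULL` keeps everything.
#' @return A `count_matrix` with metadata subset in step.
#' @export
subset_cm <- function(x, genes = NULL, cells = NULL) {
  gi <- if (is.null(genes)) seq_len(nrow(x$counts)) else genes
  ci <- if (is.null(cells)) seq_len(ncol(x$counts)) else cells
  if (is.character(gi)) gi <- match(gi, rownames(x$counts))
  if (is.character(ci)) ci <- match(ci, colnames(x$counts))
  count_matrix(
    x$counts[gi, ci, drop = FALSE],
    gene_meta = x$gene_meta[if (is.logical(gi)) which(gi) else gi, , drop = FALSE],
    cell_meta = x$cell_meta[if (is.logical(ci)) which(ci) else ci, , drop = FALSE]
  )
}

#' Write a count matrix as Matrix Market plus TSV annotation files
#'
#' Writes `matrix.mtx` (sparse Matrix Market coordinate format),
#' `genes.tsv` (columns `gene_id`, `mito`) and `cells.tsv` (all cell
#' metadata columns) into `dir`.
#'
#' @param x A `count_matrix`.
#' @param dir Output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::Matrix(x$counts, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  utils::write.table(x$gene_meta, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$cell_meta, file.path(dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param dir Directory holding `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return A `count_matrix`.
#' @export
read_count_matrix <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("no matrix.mtx under '", dir, "'", call. = FALSE)
  m <- as.matrix(Matrix::readMM(mtx))
  genes <- utils::read.delim(file.path(dir, "genes.tsv"), stringsAsFactors = FALSE)
  cells <- utils::read.delim(file.path(dir, "cells.tsv"), stringsAsFactors = FALSE)
  genes$mito <- as.logical(genes$mito)
  dimnames(m) <- list(genes$gene_id, cells$cell_id)
  count_matrix(m, gene_meta = genes, cell_meta = cells)
}

#' Read a dense CSV count matrix (genes in rows, cells in columns)
#'
#' Fallback reader for small dense matrices; the first column holds gene
#' ids, remaining column names are cell ids.  Mitochondrial genes are
#' identified by name prefix.
#'
#' @param path CSV file.
#' @param cell_meta Optional cell metadata `data.frame` (must contain
#'   `cell_id` matching the columns).
#' @param mito_prefix Gene-name prefix flagging mitochondrial genes.
#' @return A `count_matrix`.
#' @export
read_count_csv <- function(path, cell_meta = NULL, mito_prefix = "mt-") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  gm <- data.frame(gene_id = rownames(m),
                   mito = startsWith(rownames(m), mito_prefix),
                   stringsAsFactors = FALSE)
  if (!is.null(cell_meta)) {
    cell_meta <- cell_meta[match(colnames(m), cell_meta$cell_id), , drop = FALSE]
  }
  count_matrix(m, gene_meta = gm, cell_meta = cell_meta)
}
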