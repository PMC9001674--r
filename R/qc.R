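#' Quality-control filter on detected genes and mitochondrial fraction
#'
#' Drops cells with fewer than `min_genes` detected genes (count > 0) or a
#' mitochondrial read fraction above `max_mito`.  Both comparisons are
#' strict, so a cell with exactly `min_genes` detected genes and exactly
#' `max_mito` mitochondrial fraction is kept.  Cells with zero total counts
#' are dropped and flagged separately.
#'
#' @param m A [count_matrix()] with mitochondrial flags in `gene_meta$mito`.
#' @param min_genes Minimum detected genes (default 2000).
#' @param max_mito Maximum mitochondrial count fraction (default 0.12).
#' @return List with `kept` (filtered `count_matrix`) and `report`
#'   (`data.frame` per cell: `cell_id`, `genes_detected`, `mito_fraction`,
#'   `zero_total`, `kept`, plus the thresholds as attributes).
#' @export
qc_filter <- function(m, min_genes = 2000, max_mito = 0.12) {
  stopifnot(inherits(m, "count_matrix"))
  counts <- as.matrix(m$counts)
  genes_detected <- colSums(counts > 0)
  total <- colSums(counts)
  mito_counts <- colSums(counts[m$gene_meta$mito, , drop = FALSE])
  mito_fraction <- ifelse(total > 0, mito_counts / total, NA_real_)
  zero_total <- total == 0
  kept <- !zero_total & genes_detected >= min_genes &
    !is.na(mito_fraction) & mito_fraction <= max_mito
  report <- data.frame(cell_id = m$cell_meta$cell_id,
                       genes_detected = as.integer(genes_detected),
                       mito_fraction = mito_fraction,
                       zero_total = zero_total,
                       kept = kept, stringsAsFactors = FALSE)
  attr(report, "min_genes") <- min_genes
  attr(report, "max_mito") <- max_mito
  list(kept = subset_cm(m, cells = which(kept)), report = report)
}

#' Filter genes by minimum expression breadth
#'
#' Keeps genes with at least `min_count` counts in at least `min_cells`
#' cells.
#'
#' @param m A [count_matrix()].
#' @param min_count Minimum per-cell count (default 100).
#' @param min_cells Minimum number of cells reaching it (default 2).
#' @return The filtered [count_matrix()].
#' @export
filter_genes <- function(m, min_count = 100, min_cells = 2) {
  stopifnot(inherits(m, "count_matrix"))
  keep <- Matrix::rowSums(m$counts >= min_count) >= min_cells
  subset_cm(m, genes = which(as.logical(keep)))
}

#' Reads-per-million normalization with log2 layer
#'
#' Scales each cell to a library size of one million reads
#' (`rpm = count / total * 1e6`) and adds a `log2(rpm + 1)` layer.  Every
#' cell must have a positive total (apply [qc_filter()] first).
#'
#' @param m A [count_matrix()].
#' @param pseudocount Added before the log2 transform (default 1).
#' @return An object of class `normalized_matrix`: list with `rpm` and
#'   `log2` gene x cell matrices plus the `gene_meta` / `cell_meta` of `m`.
#' @export
rpm_log2 <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "count_matrix"))
  counts <- as.matrix(m$counts)
  total <- colSums(counts)
  if (any(total == 0))
    stop("cells with zero total counts present; run qc_filter first",
         call. = FALSE)
  rpm <- sweep(counts, 2, total, "/") * 1e6
  structure(list(rpm = rpm, log2 = log2(rpm + pseudocount),
                 gene_meta = m$gene_meta, cell_meta = m$cell_meta),
            class = "normalized_matrix")
}

#' Long-format radial expression table for selected genes
#'
#' For each requested gene, min-max normalizes its log2 expression across
#' cells to `[0, 1]` and emits one record per cell sorted by the cell's
#' recorded radial position — the numeric backbone of a depth-by-expression
#' gradient plot.  Genes with constant expression are emitted as all-zero
#' and flagged.
#'
#' @param nm A `normalized_matrix` (see [rpm_log2()]) whose `cell_meta` has
#'   `radial_position`.
#' @param genes Character vector of gene ids present in the matrix.
#' @return `data.frame` with `cell_id`, `radial_position`, `gene`,
#'   `normalized_value` (in `[0, 1]`) and logical `constant`.
#' @export
radial_expression_table <- function(nm, genes) {
  stopifnot(inherits(nm, "normalized_matrix"))
  if (!"radial_position" %in% names(nm$cell_meta) ||
      all(is.na(nm$cell_meta$radial_position)))
    stop("cells carry no recorded radial_position", call. = FALSE)
  missing <- setdiff(genes, rownames(nm$log2))
  if (length(missing))
    stop("genes absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  ord <- order(nm$cell_meta$radial_position)
  recs <- lapply(genes, function(g) {
    v <- nm$log2[g, ord]
    rng <- range(v)
    constant <- rng[1] == rng[2]
    nv <- if (constant) rep(0, length(v)) else (v - rng[1]) / (rng[2] - rng[1])
    data.frame(cell_id = nm$cell_meta$cell_id[ord],
               radial_position = nm$cell_meta$radial_position[ord],
               gene = g, normalized_value = nv, constant = constant,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}
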