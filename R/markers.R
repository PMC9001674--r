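#' Early variable-gene set from two birthdate rankings
#'
#' Takes the top `top_k` variable genes of each of two rankings (e.g. the
#' E12-born and E13-born neuron rankings), combines them, and deduplicates
#' genes present in both lists so each appears once; with `top_k = 50` and
#' an overlap of 11 the union holds 89 genes.
#'
#' @param rank_a,rank_b `data.frame`s from [select_variable_genes()] (or
#'   any with `gene_id` ordered by rank).
#' @param top_k Genes taken from each ranking (default 50).
#' @return Character vector of the deduplicated union, with attributes
#'   `overlap` (count present in both lists) and `size`
#'   (`2 * top_k - overlap`).
#' @export
early_variable_gene_set <- function(rank_a, rank_b, top_k = 50) {
  stopifnot(nrow(rank_a) >= top_k, nrow(rank_b) >= top_k)
  a <- utils::head(rank_a$gene_id, top_k)
  b <- utils::head(rank_b$gene_id, top_k)
  genes <- union(a, b)
  structure(genes, overlap = length(intersect(a, b)), size = length(genes))
}

#' Per-group expression profile normalized to [0, 1] per gene
#'
#' Group means of `log2(RPM + 1)` expression, min-max scaled across groups
#' per gene: each row spans 0 (group with the lowest mean) to 1 (highest).
#' Constant genes yield an all-zero row and are flagged.
#'
#' @param nm A `normalized_matrix` (see [rpm_log2()]).
#' @param gene_set Character vector of gene ids.
#' @param groups Factor/character vector assigning each cell to a group.
#' @return Numeric gene x group matrix in `[0, 1]` with logical attribute
#'   `constant` per gene.
#' @export
normalized_group_profile <- function(nm, gene_set, groups) {
  stopifnot(inherits(nm, "normalized_matrix"),
            length(groups) == ncol(nm$log2))
  missing <- setdiff(gene_set, rownames(nm$log2))
  if (length(missing))
    stop("genes absent: ", paste(missing, collapse = ", "), call. = FALSE)
  gl <- sort(unique(as.character(groups)))
  means <- vapply(gl, function(g)
    rowMeans(nm$log2[gene_set, groups == g, drop = FALSE]),
    numeric(length(gene_set)))
  means <- matrix(means, nrow = length(gene_set),
                  dimnames = list(gene_set, gl))
  rng <- t(apply(means, 1, range))
  constant <- rng[, 1] == rng[, 2]
  prof <- (means - rng[, 1]) / ifelse(constant, 1, rng[, 2] - rng[, 1])
  prof[constant, ] <- 0
  attr(prof, "constant") <- constant
  prof
}

#' Expression thresholds for late-born neuron markers
#'
#' Threshold per marker = mean RPM over the cells of the designated
#' late-born reference clusters.
#'
#' @param nm A `normalized_matrix`.
#' @param assign Cluster assignment (object or integer vector).
#' @param late_clusters Cluster ids of the late-born reference clusters.
#' @param markers Character vector of marker gene ids.
#' @return `data.frame`: `marker`, `threshold` (RPM), `n_reference_cells`,
#'   logical `missing` for markers absent from the matrix.
#' @export
late_marker_thresholds <- function(nm, assign, late_clusters, markers) {
  stopifnot(inherits(nm, "normalized_matrix"), length(late_clusters) >= 1)
  cl <- if (inherits(assign, "cluster_assignment")) assign$cluster else assign
  ref <- cl %in% late_clusters
  if (!any(ref)) stop("no cells in the designated late clusters", call. = FALSE)
  present <- markers %in% rownames(nm$rpm)
  thr <- rep(NA_real_, length(markers))
  thr[present] <- rowMeans(nm$rpm[markers[present], ref, drop = FALSE])
  data.frame(marker = markers, threshold = thr,
             n_reference_cells = sum(ref), missing = !present,
             stringsAsFactors = FALSE)
}

#' Fraction of expressing cells above a marker threshold
#'
#' Among the cells of a group with marker RPM strictly greater than 0 (the
#' dropout guard), the fraction with RPM strictly greater than the marker's
#' threshold.
#'
#' @param nm A `normalized_matrix`.
#' @param thresholds `data.frame` from [late_marker_thresholds()].
#' @param group_cells Logical or integer index of the group's cells.
#' @return `data.frame`: `marker`, `threshold`, `n_expressing`
#'   (denominator), `n_above` (numerator), `fraction` (`NA` when no cell
#'   expresses the marker).
#' @export
marker_positive_fraction <- function(nm, thresholds, group_cells) {
  stopifnot(inherits(nm, "normalized_matrix"))
  rows <- lapply(seq_len(nrow(thresholds)), function(i) {
    mk <- thresholds$marker[i]; thr <- thresholds$threshold[i]
    if (is.na(thr) || !mk %in% rownames(nm$rpm)) {
      return(data.frame(marker = mk, threshold = thr, n_expressing = NA_integer_,
                        n_above = NA_integer_, fraction = NA_real_))
    }
    v <- nm$rpm[mk, group_cells]
    expr <- v > 0
    data.frame(marker = mk, threshold = thr,
               n_expressing = sum(expr), n_above = sum(v[expr] > thr),
               fraction = if (any(expr)) sum(v[expr] > thr) / sum(expr)
                          else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Choose late-born reference clusters automatically
#'
#' Picks the `n` clusters with the largest fraction of late-born
#' (default E14/E15) cells.
#'
#' @param assign Cluster assignment (object or integer vector).
#' @param birthdates Per-cell birthdates aligned with the assignment.
#' @param late Birthdate labels counted as late-born.
#' @param n Number of clusters returned (default 2).
#' @return Integer vector of cluster ids.
#' @export
pick_late_clusters <- function(assign, birthdates, late = c("E14", "E15"),
                               n = 2) {
  comp <- composition(assign, birthdates)
  late_frac <- rowSums(comp$fractions[, colnames(comp$fractions) %in% late,
                                      drop = FALSE])
  as.integer(names(sort(late_frac, decreasing = TRUE)[seq_len(min(n, length(late_frac)))]))
}
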