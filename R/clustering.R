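#' Graph-based clustering of neurons
#'
#' Standard single-cell community-detection pipeline: the top
#' `n_var_genes` variable genes (vst ranking on raw counts) feed a PCA of
#' the per-gene scaled `log2(RPM + 1)` values; a k-nearest-neighbor graph
#' in the space of the leading `dims` principal components is reweighted
#' by shared-nearest-neighbor Jaccard similarity; Louvain modularity
#' optimization at the given `resolution` yields the communities.
#' Deterministic given `seed`.
#'
#' @param m A [count_matrix()] of raw counts.
#' @param n_var_genes Variable genes used (default 2000; capped at the
#'   number of genes with nonzero variance).
#' @param dims Number of leading principal components (default 15; capped
#'   at what the data support).
#' @param resolution Modularity resolution (default 1.0).
#' @param k_neighbors Neighbors of the kNN graph (default 20).
#' @param prune Minimum Jaccard weight retained as an edge (default 1/15).
#' @param seed Integer seed for the community search.
#' @return An object of class `cluster_assignment`: list with `cluster`
#'   (named integer vector, ids 1..K), `K`, `modularity`, `params` and
#'   `pca` (the cells x dims score matrix).
#' @export
cluster_neurons <- function(m, n_var_genes = 2000, dims = 15,
                            resolution = 1.0, k_neighbors = 20,
                            prune = 1 / 15, seed = 1L) {
  stopifnot(inherits(m, "count_matrix"))
  n <- ncol(m$counts)
  if (n < k_neighbors + 1)
    stop("need more cells than k_neighbors", call. = FALSE)
  counts <- as.matrix(m$counts)
  vg <- select_variable_genes(counts, k = min(n_var_genes,
                                              sum(apply(counts, 1, stats::var) > 0)))
  top <- vg$gene_id[vg$top]
  nm <- rpm_log2(count_matrix(counts, m$gene_meta, m$cell_meta))
  x <- t(nm$log2[top, , drop = FALSE])          # cells x genes
  sds <- apply(x, 2, stats::sd)
  x <- x[, sds > 0, drop = FALSE]
  dims <- min(dims, ncol(x) - 1, nrow(x) - 1)
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  emb <- p$x[, seq_len(dims), drop = FALSE]

  ## kNN then shared-nearest-neighbor Jaccard weights
  d <- as.matrix(stats::dist(emb))
  nbrs <- lapply(seq_len(n), function(i) {
    ## the cell itself plus its k nearest neighbors
    c(i, order(d[i, ])[2:(k_neighbors + 1)])
  })
  edges <- list(); w <- list(); e <- 0L
  for (i in seq_len(n)) {
    for (j in nbrs[[i]][-1]) {
      if (j > i || !(i %in% nbrs[[j]])) {
        ov <- length(intersect(nbrs[[i]], nbrs[[j]]))
        jac <- ov / (2 * (k_neighbors + 1) - ov)
        if (jac >= prune) {
          e <- e + 1L
          edges[[e]] <- c(i, j); w[[e]] <- jac
        }
      }
    }
  }
  if (e == 0) stop("SNN graph has no edges; lower prune or k", call. = FALSE)
  em <- do.call(rbind, edges)
  ## undirected simple graph; duplicate i-j / j-i pairs collapse to one edge
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  igraph::E(g)$weight <- unlist(w)
  g <- igraph::simplify(g, edge.attr.comb = "first")
  cl <- with_seed(seed,
    igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                            resolution = resolution))
  memb <- igraph::membership(cl)
  ## relabel clusters by decreasing size for stable ids
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  cluster <- as.integer(relab[as.character(memb)])
  names(cluster) <- colnames(counts)
  structure(list(cluster = cluster, K = length(sizes),
                 modularity = igraph::modularity(cl),
                 params = list(n_var_genes = n_var_genes, dims = dims,
                               resolution = resolution,
                               k_neighbors = k_neighbors, prune = prune,
                               seed = seed),
                 pca = emb),
            class = "cluster_assignment")
}

#' Birthdate composition of clusters
#'
#' Contingency counts and row-normalized fractions of cells per cluster by
#' birthdate.
#'
#' @param assign A `cluster_assignment` (see [cluster_neurons()]) or an
#'   integer vector of cluster ids.
#' @param birthdates Character vector of per-cell birthdates, aligned with
#'   the assignment.
#' @return List with `counts` and `fractions` (cluster x birthdate
#'   matrices; fractions sum to 1 per cluster).
#' @export
composition <- function(assign, birthdates) {
  cl <- if (inherits(assign, "cluster_assignment")) assign$cluster else assign
  stopifnot(length(cl) == length(birthdates))
  tab <- table(cluster = cl, birthdate = birthdates)
  counts <- unclass(tab)
  fractions <- counts / rowSums(counts)
  list(counts = counts, fractions = fractions)
}

#' One-vs-rest marker genes per cluster
#'
#' For each cluster, genes are screened by a Wilcoxon rank-sum test of the
#' cluster's cells against all remaining cells on `log2(RPM + 1)` values,
#' ranked by one-vs-rest log2 fold change (of mean RPM, with a pseudocount),
#' and reported with Benjamini-Hochberg adjusted p values.
#'
#' @param nm A `normalized_matrix` (see [rpm_log2()]).
#' @param assign Cluster assignment (object or integer vector).
#' @param n_top Markers reported per cluster (default 10).
#' @param pseudocount Added to mean RPM before the fold-change log.
#' @return `data.frame`: `cluster`, `gene_id`, `log2fc`, `p_value`,
#'   `p_adj`, `rank`.  Singleton clusters are skipped with a warning.
#' @export
cluster_markers <- function(nm, assign, n_top = 10, pseudocount = 1) {
  stopifnot(inherits(nm, "normalized_matrix"))
  cl <- if (inherits(assign, "cluster_assignment")) assign$cluster else assign
  ks <- sort(unique(cl))
  if (length(ks) < 2) stop("need >= 2 clusters", call. = FALSE)
  out <- list()
  for (k in ks) {
    in_k <- cl == k
    if (sum(in_k) < 2) {
      warning("cluster ", k, " has a single cell; skipped", call. = FALSE)
      next
    }
    mu_in <- rowMeans(nm$rpm[, in_k, drop = FALSE])
    mu_out <- rowMeans(nm$rpm[, !in_k, drop = FALSE])
    lfc <- log2((mu_in + pseudocount) / (mu_out + pseudocount))
    pv <- apply(nm$log2, 1, function(v) {
      if (stats::sd(v) == 0) return(1)
      suppressWarnings(stats::wilcox.test(v[in_k], v[!in_k],
                                          exact = FALSE)$p.value)
    })
    padj <- stats::p.adjust(pv, method = "BH")
    ord <- order(-lfc, pv)
    top <- utils::head(ord, n_top)
    out[[as.character(k)]] <- data.frame(
      cluster = k, gene_id = rownames(nm$rpm)[top],
      log2fc = lfc[top], p_value = pv[top], p_adj = padj[top],
      rank = seq_along(top), stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
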