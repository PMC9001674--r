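## Independent brute-force oracles used to cross-check the implementation.
## These deliberately re-derive each predicate/statistic from first
## principles rather than calling the functions they verify.

## direct-born gate: explicit set construction per section
oracle_gate_direct_born <- function(cells, brdu_pct = 0.20) {
  keep <- logical(nrow(cells))
  for (s in unique(cells$section_id)) {
    idx <- which(cells$section_id == s)
    ft <- cells$ft_intensity[idx]
    brdu <- cells$brdu_intensity[idx]
    med <- stats::median(ft)
    cut <- stats::quantile(brdu, brdu_pct, names = FALSE)
    for (i in idx) {
      keep[i] <- cells$ft_intensity[i] > med && cells$brdu_intensity[i] < cut
    }
  }
  which(keep)
}

## QC predicate evaluated cell by cell
oracle_qc_keep <- function(counts, mito_flag, min_genes, max_mito) {
  kept <- logical(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    det <- sum(counts[, j] > 0)
    tot <- sum(counts[, j])
    if (tot == 0) { kept[j] <- FALSE; next }
    mf <- sum(counts[mito_flag, j]) / tot
    kept[j] <- !(det < min_genes || mf > max_mito)
  }
  which(kept)
}

## gene-breadth predicate evaluated gene by gene
oracle_gene_keep <- function(counts, min_count, min_cells) {
  which(vapply(seq_len(nrow(counts)), function(g)
    sum(counts[g, ] >= min_count) >= min_cells, logical(1)))
}

## two-sample KS statistic by brute-force ECDF sweep
oracle_ks_stat <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

## nearest-point polyline distance by dense resampling
oracle_polyline_dist <- function(px, py, poly, n_dense = 20000) {
  seg_len <- sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2)
  s <- c(0, cumsum(seg_len))
  t <- seq(0, s[length(s)], length.out = n_dense)
  dx <- stats::approx(s, poly[, 1], xout = t)$y
  dy <- stats::approx(s, poly[, 2], xout = t)$y
  vapply(seq_along(px), function(i)
    sqrt(min((dx - px[i])^2 + (dy - py[i])^2)), numeric(1))
}

## PC1 fraction via SVD of the centered/scaled matrix
oracle_pc1_svd <- function(x, scale = TRUE) {
  sds <- apply(x, 2, stats::sd)
  if (scale) x <- x[, sds > 0, drop = FALSE]
  xc <- scale(x, center = TRUE, scale = scale)
  s <- svd(xc)$d^2
  s[1] / sum(s)
}

## marker-positive fraction among expressing cells, by direct counting
oracle_marker_fraction <- function(v, thr) {
  expr <- v[v > 0]
  if (!length(expr)) return(NA_real_)
  sum(expr > thr) / length(expr)
}

## small random detected-cell table spanning several sections
random_cell_table <- function(n, n_sections = 3) {
  data.frame(
    section_id = sample(paste0("s", seq_len(n_sections)), n, replace = TRUE),
    x = runif(n, 0, 100), y = runif(n, 0, 100),
    ft_intensity = rlnorm(n, 4, 1),
    brdu_intensity = rlnorm(n, 3, 1.2),
    size = runif(n, 30, 120)
  )
}

## small random count matrix with a leading mito block
random_count_matrix <- function(n_genes = 60, n_cells = 25, n_mito = 4) {
  counts <- matrix(rnbinom(n_genes * n_cells, mu = 4, size = 1), n_genes)
  ids <- c(sprintf("mt-g%02d", seq_len(n_mito)),
           sprintf("g%03d", seq_len(n_genes - n_mito)))
  dimnames(counts) <- list(ids, sprintf("c%03d", seq_len(n_cells)))
  count_matrix(counts)
}
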