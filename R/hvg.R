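#' Rank genes by standardized variance (vst method)
#'
#' Re-implementation of the "vst" highly-variable-gene ranking: per-gene
#' mean and variance of raw counts are computed; `log10(variance)` is
#' regressed on `log10(mean)` by local polynomial regression (loess, span
#' 0.3, degree 2) over genes with positive mean and variance; each gene's
#' counts are standardized with its observed mean and the square root of
#' its trend-expected variance, clipped at `sqrt(n_cells)`; the variance of
#' the clipped standardized values is the ranking statistic.  Ties are
#' broken deterministically by gene id.
#'
#' @param m A [count_matrix()] (raw counts) or a plain genes x cells
#'   numeric matrix.
#' @param k Number of top genes to flag.
#' @param loess_span,loess_degree Parameters of the mean-variance trend fit.
#' @return `data.frame` (one row per gene, ordered by rank): `gene_id`,
#'   `mean`, `variance`, `expected_variance`, `standardized_variance`,
#'   `rank`, and logical `top` marking the `k` highest-ranked genes.
#' @export
select_variable_genes <- function(m, k, loess_span = 0.3, loess_degree = 2) {
  counts <- if (inherits(m, "count_matrix")) as.matrix(m$counts) else as.matrix(m)
  n <- ncol(counts)
  if (n < 2) stop("need at least 2 cells", call. = FALSE)
  mu <- rowMeans(counts)
  v <- apply(counts, 1, stats::var)
  n_usable <- sum(v > 0)
  if (k > n_usable)
    stop("k = ", k, " exceeds the ", n_usable,
         " genes with nonzero variance", call. = FALSE)

  fit_idx <- mu > 0 & v > 0
  lx <- log10(mu[fit_idx]); ly <- log10(v[fit_idx])
  fit <- stats::loess(ly ~ lx, span = loess_span, degree = loess_degree,
                      family = "gaussian")
  exp_var <- rep(NA_real_, length(mu))
  exp_var[fit_idx] <- 10^stats::predict(fit, newdata = data.frame(lx = lx))
  ## genes the trend cannot be evaluated for (zero mean or variance) carry
  ## zero standardized variance
  std_var <- numeric(length(mu))
  clip <- sqrt(n)
  ok <- which(fit_idx & is.finite(exp_var) & exp_var > 0)
  if (length(ok)) {
    z <- sweep(counts[ok, , drop = FALSE], 1, mu[ok], "-")
    z <- sweep(z, 1, sqrt(exp_var[ok]), "/")
    z <- pmin(pmax(z, -clip), clip)
    std_var[ok] <- rowSums((z - rowMeans(z))^2) / (n - 1)
  }
  gid <- rownames(counts) %||% sprintf("gene%05d", seq_along(mu))
  ord <- order(-std_var, gid)
  rank <- integer(length(ord)); rank[ord] <- seq_along(ord)
  out <- data.frame(gene_id = gid, mean = mu, variance = v,
                    expected_variance = exp_var,
                    standardized_variance = std_var,
                    rank = rank, top = rank <= k,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$rank), ]
}
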