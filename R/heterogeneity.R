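#' Fraction of variance explained by the first principal component
#'
#' PCA on a cells x genes matrix of normalized expression values (per-gene
#' centered, and unit-scaled when `scale = TRUE`); returns
#' `lambda_1 / sum(lambda)` over the gene-gene covariance spectrum.
#'
#' @param x Numeric matrix, cells in rows, selected genes in columns
#'   (typically `log2(RPM + 1)` values).
#' @param scale Scale genes to unit variance before PCA (default `TRUE`).
#'   Constant genes are dropped before scaling.
#' @return Proportion in `(0, 1]`.
#' @export
pc1_fraction <- function(x, scale = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("need >= 2 cells and >= 2 genes", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) stop("all genes constant; PCA undefined", call. = FALSE)
  if (scale) x <- x[, sds > 0, drop = FALSE]
  if (ncol(x) < 2) stop("fewer than 2 varying genes", call. = FALSE)
  p <- stats::prcomp(x, center = TRUE, scale. = scale)
  ev <- p$sdev^2
  ev[1] / sum(ev)
}

#' Independently permute each gene across cells
#'
#' Destroys gene-gene covariance while exactly preserving every gene's
#' marginal distribution: each column (gene) of the cells x genes matrix is
#' shuffled across cells with its own independent permutation.
#'
#' @param x Numeric matrix, cells in rows, genes in columns.
#' @param seed Integer seed making the shuffle reproducible.
#' @return Matrix of the same shape with permuted columns.
#' @export
permute_genes <- function(x, seed) {
  x <- as.matrix(x)
  with_seed(seed, {
    for (j in seq_len(ncol(x))) x[, j] <- x[sample.int(nrow(x)), j]
    x
  })
}

#' Within-condition molecular heterogeneity by actual-vs-permuted PC1 ratio
#'
#' Quantifies how much cell-to-cell structure a condition carries beyond
#' chance.  Per cross-validation: `n_cells` cells of the condition are
#' subsampled without replacement; the `k_genes` most variable genes are
#' selected on that subsample ([select_variable_genes()], raw counts); the
#' variance explained by PC1 of the `log2(RPM + 1)` values of those genes
#' is computed on the actual data and again after independently shuffling
#' each gene across cells; the ratio actual / permuted is recorded.  A
#' ratio of 1 means PC1 captures no more variance than expected by chance;
#' ratios above 1 indicate latent structure (e.g. co-regulated subtype
#' programs).
#'
#' @param m A [count_matrix()] of raw counts (gene-filtered, see
#'   [filter_genes()]).
#' @param condition Label selecting cells via `cell_meta[[condition_col]]`.
#' @param condition_col Metadata column holding condition labels
#'   (default `"condition"`).
#' @param n_cells Cells per cross-validation (default 80).
#' @param k_genes Variable genes per cross-validation (default 80).
#' @param n_reps Cross-validations (default 100).
#' @param seed Master seed; per-rep seeds are fanned out with
#'   [fan_out_seeds()] so any repetition can be reproduced in isolation.
#' @param scale Unit-scale genes before PCA (default `TRUE`).
#' @param genes_per_rep Re-select variable genes within every subsample
#'   (default `TRUE`); `FALSE` selects once on all cells of the condition.
#' @return An object of class `heterogeneity_run`: list with `condition`,
#'   `params`, and `reps` (`data.frame`: `rep`, `seed`, `actual_pc1`,
#'   `permuted_pc1`, `ratio`).
#' @export
heterogeneity_ratio <- function(m, condition, condition_col = "condition",
                                n_cells = 80, k_genes = 80, n_reps = 100,
                                seed = 1L, scale = TRUE,
                                genes_per_rep = TRUE) {
  stopifnot(inherits(m, "count_matrix"))
  if (!condition_col %in% names(m$cell_meta))
    stop("no metadata column '", condition_col, "'", call. = FALSE)
  idx <- which(m$cell_meta[[condition_col]] == condition)
  if (length(idx) < n_cells)
    stop("condition '", condition, "' has ", length(idx), " cells; ",
         n_cells - length(idx), " short of the ", n_cells, " required",
         call. = FALSE)
  counts <- as.matrix(m$counts)[, idx, drop = FALSE]
  total <- colSums(counts)
  if (any(total == 0)) stop("zero-total cells present; QC first", call. = FALSE)
  log_rpm <- log2(sweep(counts, 2, total, "/") * 1e6 + 1)

  global_top <- NULL
  if (!genes_per_rep) {
    vg <- select_variable_genes(counts, k = k_genes)
    global_top <- vg$gene_id[vg$top]
  }

  seeds <- fan_out_seeds(seed, n_reps)
  reps <- lapply(seq_len(n_reps), function(r) {
    with_seed(seeds[r], {
      sub <- sample.int(ncol(counts), n_cells)
      top <- if (genes_per_rep) {
        vg <- select_variable_genes(counts[, sub, drop = FALSE], k = k_genes)
        vg$gene_id[vg$top]
      } else global_top
      x <- t(log_rpm[top, sub, drop = FALSE])   # cells x genes
      actual <- pc1_fraction(x, scale = scale)
      perm_seed <- sample.int(.Machine$integer.max - 1L, 1L)
      permuted <- pc1_fraction(permute_genes(x, perm_seed), scale = scale)
      data.frame(rep = r, seed = seeds[r], actual_pc1 = actual,
                 permuted_pc1 = permuted, ratio = actual / permuted)
    })
  })
  structure(list(condition = condition,
                 params = list(n_cells = n_cells, k_genes = k_genes,
                               n_reps = n_reps, seed = seed, scale = scale,
                               genes_per_rep = genes_per_rep),
                 reps = do.call(rbind, reps)),
            class = "heterogeneity_run")
}

#' @export
print.heterogeneity_run <- function(x, ...) {
  cat(sprintf("<heterogeneity_run> %s: mean ratio %.3f (median %.3f, n_reps %d)\n",
              x$condition, mean(x$reps$ratio), stats::median(x$reps$ratio),
              nrow(x$reps)))
  invisible(x)
}

#' Summarize and compare heterogeneity runs across conditions
#'
#' Produces a per-run summary table and two contrasts: an early (E12/E13)
#' versus late (E14/E15) epoch contrast per stage via a two-way
#' repeated-measures ANOVA (epoch as the tested factor, condition as the
#' repeated unit over cross-validations; delegated to [stats::aov()]), and
#' a deep-layer versus superficial-layer contrast via a two-sided
#' Mann-Whitney test on the pooled per-repetition ratios.
#'
#' @param runs List of `heterogeneity_run` objects (>= 2).
#' @param early,late Character vectors of birthdate labels defining the
#'   epochs (defaults `c("E12","E13")` / `c("E14","E15")`).
#' @param dl_conditions,sl_conditions Condition labels of the adult
#'   deep-layer and superficial-layer runs, if present.
#' @return List with `summary` (`data.frame`: `condition`, `n_reps`,
#'   `mean_ratio`, `median_ratio`, `iqr_ratio`), `epoch_tests` (per-stage
#'   `data.frame` with `F`, `df1`, `df2`, `p_value`, `method`) and
#'   `dl_vs_sl` (list with `U`, `p_value`, medians) or `NULL`.
#' @export
compare_heterogeneity <- function(runs,
                                  early = c("E12", "E13"),
                                  late = c("E14", "E15"),
                                  dl_conditions = NULL,
                                  sl_conditions = NULL) {
  stopifnot(length(runs) >= 2)
  summary <- do.call(rbind, lapply(runs, function(r) {
    q <- interp_quantile(r$reps$ratio, c(0.25, 0.75))
    data.frame(condition = r$condition, n_reps = nrow(r$reps),
               mean_ratio = mean(r$reps$ratio),
               median_ratio = stats::median(r$reps$ratio),
               iqr_ratio = q[2] - q[1], stringsAsFactors = FALSE)
  }))
  long <- do.call(rbind, lapply(runs, function(r) {
    data.frame(condition = r$condition, rep = r$reps$rep,
               ratio = r$reps$ratio, stringsAsFactors = FALSE)
  }))
  parts <- strsplit(long$condition, "_", fixed = TRUE)
  long$birthdate <- vapply(parts, `[`, character(1), 1)
  long$stage <- vapply(parts, function(p)
    if (length(p) > 1) paste(p[-1], collapse = "_") else NA_character_,
    character(1))
  long$epoch <- ifelse(long$birthdate %in% early, "early",
                       ifelse(long$birthdate %in% late, "late", NA))

  epoch_tests <- NULL
  for (st in unique(stats::na.omit(long$stage))) {
    df <- long[!is.na(long$epoch) & long$stage %in% st, ]
    if (length(unique(df$epoch)) < 2) next
    balanced <- length(unique(table(df$condition))) == 1 &&
      length(unique(table(df$epoch[!duplicated(df$condition)]))) == 1
    if (balanced) {
      av <- stats::aov(ratio ~ epoch + Error(condition), data = df)
      tab <- summary(av)[["Error: condition"]][[1]]
      res <- data.frame(stage = st, F = tab["epoch", "F value"],
                        df1 = tab["epoch", "Df"],
                        df2 = tab["Residuals", "Df"],
                        p_value = tab["epoch", "Pr(>F)"],
                        method = "two-way RM ANOVA",
                        stringsAsFactors = FALSE)
    } else {
      warning("unbalanced design for stage '", st,
              "'; falling back to Welch contrast", call. = FALSE)
      tt <- stats::t.test(ratio ~ epoch, data = df, var.equal = FALSE)
      res <- data.frame(stage = st, F = unname(tt$statistic)^2,
                        df1 = 1, df2 = unname(tt$parameter),
                        p_value = tt$p.value, method = "Welch t",
                        stringsAsFactors = FALSE)
    }
    epoch_tests <- rbind(epoch_tests, res)
  }

  dl_vs_sl <- NULL
  if (!is.null(dl_conditions) && !is.null(sl_conditions)) {
    dl <- long$ratio[long$condition %in% dl_conditions]
    sl <- long$ratio[long$condition %in% sl_conditions]
    if (length(dl) && length(sl)) {
      wt <- stats::wilcox.test(dl, sl, alternative = "two.sided", exact = FALSE)
      dl_vs_sl <- list(U = unname(wt$statistic), p_value = wt$p.value,
                       median_dl = stats::median(dl),
                       median_sl = stats::median(sl))
    }
  }
  list(summary = summary, epoch_tests = epoch_tests, dl_vs_sl = dl_vs_sl)
}
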