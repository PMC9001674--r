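test_that("pc1_fraction matches the SVD oracle and handles rank-1 input", {
  withr::local_seed(61)
  for (i in 1:10) {
    x <- matrix(rnorm(40 * 8), 40)
    expect_equal(pc1_fraction(x, scale = TRUE),
                 oracle_pc1_svd(x, scale = TRUE), tolerance = 1e-9)
    expect_equal(pc1_fraction(x, scale = FALSE),
                 oracle_pc1_svd(x, scale = FALSE), tolerance = 1e-9)
  }
  ## two perfectly correlated genes: all variance on PC1
  v <- rnorm(30)
  expect_equal(pc1_fraction(cbind(v, 2 * v + 1)), 1)
  expect_error(pc1_fraction(matrix(1, 5, 3)), "constant")
})

test_that("pc1_fraction of isotropic noise matches a Wishart simulation", {
  withr::local_seed(62)
  obs <- pc1_fraction(matrix(rnorm(500 * 10), 500), scale = TRUE)
  sim <- replicate(200, {
    s <- svd(scale(matrix(rnorm(500 * 10), 500)))$d^2
    s[1] / sum(s)
  })
  expect_lt(abs(obs - mean(sim)), 3 * sd(sim))
})

test_that("gene permutation preserves marginals and kills correlation", {
  withr::local_seed(63)
  x <- matrix(rnorm(200 * 6), 200)
  x[, 2] <- x[, 1] + rnorm(200, 0, 0.1)      # strong gene-gene correlation
  p <- permute_genes(x, seed = 5)
  expect_identical(permute_genes(x, seed = 5), p)
  for (j in 1:6) expect_equal(sort(p[, j]), sort(x[, j]))
  expect_identical(permute_genes(x[1, , drop = FALSE], 9),
                   x[1, , drop = FALSE])
  ## mean off-diagonal correlation near zero over Monte-Carlo repeats
  rbar <- mean(replicate(50, {
    pp <- permute_genes(x, sample.int(1e6, 1))
    cc <- cor(pp); mean(cc[upper.tri(cc)])
  }))
  expect_lt(abs(rbar), 0.02)
})

make_condition_cm <- function(k, logfc, n_cells = 200, seed = 71,
                              label = "E13_N1d") {
  es <- expr_sim_spec(n_genes = 800, conditions = list(
    sim_condition(label, n_cells = n_cells, k_subtypes = k,
                  effect_logfc = logfc)), seed = seed)
  filter_genes(simulate_counts(es), min_count = 5, min_cells = 2)
}

test_that("heterogeneity run is reproducible and internally consistent", {
  cm <- make_condition_cm(1, 0, n_cells = 120)
  h1 <- heterogeneity_ratio(cm, "E13_N1d", n_cells = 60, k_genes = 40,
                            n_reps = 8, seed = 3)
  h2 <- heterogeneity_ratio(cm, "E13_N1d", n_cells = 60, k_genes = 40,
                            n_reps = 8, seed = 3)
  expect_identical(h1$reps, h2$reps)
  expect_equal(h1$reps$ratio, h1$reps$actual_pc1 / h1$reps$permuted_pc1)
  expect_true(all(h1$reps$actual_pc1 > 0 & h1$reps$actual_pc1 <= 1))
  expect_error(heterogeneity_ratio(cm, "E13_N1d", n_cells = 1000),
               "short")
  expect_error(heterogeneity_ratio(cm, "nope"), "has 0 cells")
})

test_that("structured conditions score above homogeneous ones", {
  hom <- make_condition_cm(1, 0, seed = 72)
  str <- make_condition_cm(3, 2, seed = 73)
  h_hom <- heterogeneity_ratio(hom, "E13_N1d", n_reps = 40, seed = 5)
  h_str <- heterogeneity_ratio(str, "E13_N1d", n_reps = 40, seed = 5)
  expect_gt(mean(h_str$reps$ratio), mean(h_hom$reps$ratio))
  wt <- wilcox.test(h_str$reps$ratio, h_hom$reps$ratio,
                    alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("feeding pre-permuted data restores the null", {
  cm <- make_condition_cm(3, 2, seed = 74)
  counts <- as.matrix(cm$counts)
  shuffled <- t(permute_genes(t(counts), seed = 99))
  dimnames(shuffled) <- dimnames(counts)
  cm_shuf <- count_matrix(shuffled, cm$gene_meta, cm$cell_meta)
  h <- heterogeneity_ratio(cm_shuf, "E13_N1d", n_reps = 40, seed = 6)
  expect_gt(mean(h$reps$ratio), 0.9)
  expect_lt(mean(h$reps$ratio), 1.1)
})

test_that("comparison summarizes runs and contrasts epochs and layers", {
  specs <- list(E12_N1d = c(3, 2), E13_N1d = c(3, 2),
                E14_N1d = c(1, 0), E15_N1d = c(1, 0),
                adult_DL = c(3, 2), adult_SL = c(1, 0))
  runs <- lapply(names(specs), function(lb) {
    cm <- make_condition_cm(specs[[lb]][1], specs[[lb]][2], n_cells = 150,
                            seed = 100 + match(lb, names(specs)), label = lb)
    heterogeneity_ratio(cm, lb, n_reps = 25, seed = 7)
  })
  cmp <- compare_heterogeneity(runs, dl_conditions = "adult_DL",
                               sl_conditions = "adult_SL")
  expect_equal(nrow(cmp$summary), 6)
  ## bookkeeping: summary means equal arithmetic means of stored ratios
  for (i in seq_along(runs)) {
    expect_equal(cmp$summary$mean_ratio[i], mean(runs[[i]]$reps$ratio))
  }
  expect_equal(cmp$epoch_tests$method[cmp$epoch_tests$stage == "N1d"],
               "two-way RM ANOVA")
  expect_lt(cmp$dl_vs_sl$p_value, 0.05)
  expect_gt(cmp$dl_vs_sl$median_dl, cmp$dl_vs_sl$median_sl)

  ## identical runs in both layer groups: p near 1
  same <- compare_heterogeneity(runs[c(5, 5)],
                                dl_conditions = "adult_DL",
                                sl_conditions = "adult_DL")
  expect_gt(same$dl_vs_sl$p_value, 0.9)
})
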