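toy_cm <- function(counts, n_mito = 2) {
  ids <- c(sprintf("mt-g%d", seq_len(n_mito)),
           sprintf("g%d", seq_len(nrow(counts) - n_mito)))
  dimnames(counts) <- list(ids, sprintf("c%d", seq_len(ncol(counts))))
  count_matrix(counts)
}

test_that("QC thresholds are strict at the boundary", {
  ## cells as columns; detected genes counted as count > 0
  n_genes <- 2100
  a <- numeric(n_genes); a[3:2001] <- 1            # 1999 detected, 0% mito
  ## 2000 detected genes, mito fraction exactly 600/5000 = 0.12
  b <- numeric(n_genes)
  b[1] <- 600; b[2] <- 2402; b[3:2000] <- 1
  counts <- cbind(a, b)
  m <- toy_cm(counts, n_mito = 1)   # cells named c1 (= a), c2 (= b)
  qc <- qc_filter(m, min_genes = 2000, max_mito = 0.12)
  rep <- qc$report
  expect_equal(rep$genes_detected, c(1999, 2000))
  ## 1999 detected genes: below 2000, dropped
  expect_false(rep$kept[rep$cell_id == "c1"])
  ## exactly 2000 genes and exactly 12.0% mito: kept (strict < and >)
  expect_equal(rep$mito_fraction[2], 0.12, tolerance = 1e-12)
  expect_true(rep$kept[rep$cell_id == "c2"])
})

test_that("QC filter equals brute-force predicate evaluation", {
  withr::local_seed(17)
  for (i in 1:15) {
    m <- random_count_matrix(n_genes = 50, n_cells = 30)
    mg <- sample(20:60, 1); mm <- runif(1, 0.05, 0.3)
    qc <- qc_filter(m, min_genes = mg, max_mito = mm)
    expect_equal(which(qc$report$kept),
                 oracle_qc_keep(as.matrix(m$counts), m$gene_meta$mito, mg, mm))
  }
})

test_that("zero-total cells are dropped and flagged separately", {
  counts <- cbind(c(0, 0, 5, 5), c(0, 0, 0, 0))
  m <- toy_cm(counts)   # cells named c1, c2
  qc <- qc_filter(m, min_genes = 1, max_mito = 1)
  expect_true(qc$report$zero_total[qc$report$cell_id == "c2"])
  expect_equal(qc$kept$cell_meta$cell_id, "c1")
})

test_that("gene filter keeps >=min_count in >=min_cells and is idempotent", {
  counts <- rbind(g1 = c(100, 100, 0, 0), g2 = c(100, 99, 0, 0),
                  g3 = c(0, 0, 0, 0), g4 = c(7, 3, 2, 1))
  dimnames(counts) <- list(rownames(counts), paste0("c", 1:4))
  m <- count_matrix(counts)
  f <- filter_genes(m, min_count = 100, min_cells = 2)
  expect_equal(f$gene_meta$gene_id, "g1")
  expect_equal(nrow(filter_genes(m, min_count = 0)$counts), nrow(counts))
  expect_equal(filter_genes(filter_genes(m, 5, 2), 5, 2),
               filter_genes(m, 5, 2))
  withr::local_seed(23)
  for (i in 1:10) {
    rm <- random_count_matrix()
    mc <- sample(1:8, 1)
    expect_equal(match(filter_genes(rm, mc, 2)$gene_meta$gene_id,
                       rm$gene_meta$gene_id),
                 oracle_gene_keep(as.matrix(rm$counts), mc, 2))
  }
})

test_that("RPM normalization conserves library size and is scale-equivariant", {
  withr::local_seed(31)
  m <- random_count_matrix(n_genes = 40, n_cells = 10)
  nm <- rpm_log2(m)
  expect_equal(unname(colSums(nm$rpm)), rep(1e6, 10), tolerance = 1e-6)
  expect_true(all(nm$log2[as.matrix(m$counts) == 0] == 0))

  ## doubling a cell's counts leaves its RPM column unchanged
  c2 <- as.matrix(m$counts); c2[, 3] <- c2[, 3] * 2L
  dimnames(c2) <- dimnames(m$counts)
  nm2 <- rpm_log2(count_matrix(c2, m$gene_meta, m$cell_meta))
  expect_equal(nm2$rpm[, 3], nm$rpm[, 3])

  z <- count_matrix(matrix(0L, 3, 2, dimnames = list(letters[1:3], c("x", "y"))))
  expect_error(rpm_log2(z), "zero total")
})

test_that("radial expression table min-max normalizes per gene", {
  counts <- rbind(g1 = c(0, 0, 50, 0), g2 = c(1, 2, 3, 4), g3 = c(5, 5, 5, 5))
  ## equalize library sizes so constant counts mean constant RPM
  counts <- rbind(counts, filler = 200 - colSums(counts))
  dimnames(counts) <- list(rownames(counts), paste0("c", 1:4))
  m <- count_matrix(counts,
                    cell_meta = data.frame(cell_id = paste0("c", 1:4),
                                           radial_position = c(0.9, 0.1, 0.5, 0.3)))
  tab <- radial_expression_table(rpm_log2(m), c("g1", "g3"))
  expect_true(all(tab$normalized_value >= 0 & tab$normalized_value <= 1))
  g1 <- tab[tab$gene == "g1", ]
  ## expressed in exactly one cell: that cell 1, others 0
  expect_equal(sort(g1$normalized_value), c(0, 0, 0, 1))
  expect_equal(g1$cell_id[which.max(g1$normalized_value)], "c3")
  ## sorted by radial position
  expect_false(is.unsorted(g1$radial_position))
  ## constant gene flagged, all zero
  g3 <- tab[tab$gene == "g3", ]
  expect_true(all(g3$constant) && all(g3$normalized_value == 0))
  expect_error(radial_expression_table(rpm_log2(m), "nope"), "absent")
})

test_that("depth-graded synthetic expression correlates with position", {
  withr::local_seed(41)
  n <- 80
  depth <- runif(n)
  base <- matrix(rnbinom(50 * n, mu = 20, size = 2), 50)
  grad <- rnbinom(n, mu = 10 + 2000 * depth, size = 100)
  counts <- rbind(base, graded = grad)
  dimnames(counts) <- list(c(sprintf("g%02d", 1:50), "graded"),
                           sprintf("c%02d", 1:n))
  m <- count_matrix(counts,
                    cell_meta = data.frame(cell_id = colnames(counts),
                                           radial_position = depth))
  tab <- radial_expression_table(rpm_log2(m), "graded")
  expect_gt(cor(tab$radial_position, tab$normalized_value,
                method = "spearman"), 0.9)
})
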