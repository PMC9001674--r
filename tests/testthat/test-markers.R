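test_that("early variable-gene set is a deduplicated union with overlap", {
  mk_rank <- function(ids) data.frame(gene_id = ids)
  a <- mk_rank(sprintf("a%02d", 1:50))
  b <- mk_rank(sprintf("b%02d", 1:50))
  disjoint <- early_variable_gene_set(a, b, top_k = 50)
  expect_length(disjoint, 100)
  expect_equal(attr(disjoint, "overlap"), 0)

  same <- early_variable_gene_set(a, a, top_k = 50)
  expect_length(same, 50)
  expect_equal(attr(same, "overlap"), 50)

  ## sharing exactly 11 genes reproduces the 2*50 - 11 = 89 arithmetic
  b11 <- mk_rank(c(sprintf("a%02d", 1:11), sprintf("b%02d", 1:39)))
  s <- early_variable_gene_set(a, b11, top_k = 50)
  expect_length(s, 89)
  expect_equal(attr(s, "overlap"), 11)

  ## property: size is always 2k - overlap
  withr::local_seed(91)
  pool <- sprintf("g%03d", 1:200)
  for (i in 1:20) {
    ra <- mk_rank(sample(pool, 60)); rb <- mk_rank(sample(pool, 60))
    k <- sample(10:50, 1)
    s <- early_variable_gene_set(ra, rb, top_k = k)
    expect_length(s, 2 * k - attr(s, "overlap"))
  }
})

group_fixture <- function(seed = 92) {
  ## planted "late program": higher expression for E14/E15 cells
  withr::local_seed(seed)
  n_per <- 30; groups <- rep(c("E12", "E13", "E14", "E15"), each = n_per)
  late <- groups %in% c("E14", "E15")
  base <- matrix(rnbinom(40 * length(groups), mu = 30, size = 3), 40)
  lateprog <- t(vapply(1:6, function(i)
    rnbinom(length(groups), mu = ifelse(late, 120, 15), size = 3),
    numeric(length(groups))))
  counts <- rbind(base, lateprog)
  dimnames(counts) <- list(c(sprintf("g%02d", 1:40), sprintf("late%d", 1:6)),
                           sprintf("c%03d", seq_along(groups)))
  list(nm = rpm_log2(count_matrix(counts)), groups = groups)
}

test_that("normalized group profile spans [0,1] and orders epochs", {
  fx <- group_fixture()
  prof <- normalized_group_profile(fx$nm, c(sprintf("late%d", 1:6), "g01"),
                                   fx$groups)
  expect_true(all(prof >= 0 & prof <= 1))
  for (g in sprintf("late%d", 1:6)) {
    expect_gt(min(prof[g, c("E14", "E15")]), max(prof[g, c("E12", "E13")]))
  }
  ## each non-constant row touches both 0 and 1
  expect_true(all(apply(prof, 1, max) == 1 | attr(prof, "constant")))
})

test_that("late-marker thresholds are local means over reference clusters", {
  counts <- rbind(m1 = c(0, 0, 10, 20, 30), m2 = c(5, 5, 0, 0, 0),
                  filler = c(95, 95, 90, 80, 70))
  dimnames(counts) <- list(rownames(counts), paste0("c", 1:5))
  nm <- rpm_log2(count_matrix(counts))
  cl <- c(1, 1, 4, 4, 5)
  thr <- late_marker_thresholds(nm, cl, late_clusters = c(4, 5),
                                markers = c("m1", "m2", "absent"))
  ## hand computation: mean RPM of m1 over cells 3-5
  expect_equal(thr$threshold[1], mean(nm$rpm["m1", 3:5]))
  expect_equal(thr$threshold[2], 0)   # m2 silent in late clusters
  expect_true(thr$missing[3])
  ## locality: cells outside the late clusters cannot move the threshold
  counts2 <- counts; counts2["m1", 1] <- 500
  nm2 <- rpm_log2(count_matrix(counts2))
  ## (same library size trick not needed: threshold uses late cells only)
  thr2 <- late_marker_thresholds(nm2, cl, c(4, 5), "m1")
  expect_equal(thr2$threshold, thr$threshold[1])
})

test_that("marker-positive fractions count expressing cells only", {
  ## toy from first principles: group RPM values 0,1,3,5, threshold 2 -> 2/3
  counts <- rbind(mk = c(0, 1, 3, 5), rest = c(1000, 999, 997, 995))
  dimnames(counts) <- list(c("mk", "rest"), paste0("c", 1:4))
  nm <- rpm_log2(count_matrix(counts))
  ## library sizes are equal so RPM is proportional to counts
  thr <- data.frame(marker = "mk", threshold = 2 / 1000 * 1e6)
  mf <- marker_positive_fraction(nm, thr, group_cells = 1:4)
  expect_equal(mf$n_expressing, 3)
  expect_equal(mf$n_above, 2)
  expect_equal(mf$fraction, 2 / 3)

  ## threshold 0: every expressing cell counts
  mf0 <- marker_positive_fraction(nm, data.frame(marker = "mk", threshold = 0),
                                  1:4)
  expect_equal(mf0$fraction, 1)

  ## no expressing cells: undefined, reported as NA
  mfe <- marker_positive_fraction(nm, thr, group_cells = 1)
  expect_true(is.na(mfe$fraction))

  ## monotonically non-increasing in the threshold + oracle agreement
  withr::local_seed(93)
  v <- rnbinom(50, mu = 8, size = 1)
  counts <- rbind(mk = v, rest = 1000 - v)
  dimnames(counts) <- list(c("mk", "rest"), sprintf("c%02d", 1:50))
  nm <- rpm_log2(count_matrix(counts))
  ths <- sort(runif(8, 0, max(nm$rpm["mk", ])))
  fr <- vapply(ths, function(t)
    marker_positive_fraction(nm, data.frame(marker = "mk", threshold = t),
                             1:50)$fraction, numeric(1))
  expect_true(all(diff(fr) <= 0))
  for (t in ths) {
    expect_equal(
      marker_positive_fraction(nm, data.frame(marker = "mk", threshold = t),
                               1:50)$fraction,
      oracle_marker_fraction(nm$rpm["mk", ], t))
  }
})

test_that("automatic late-cluster pick maximizes the late-born fraction", {
  cl <- rep(1:3, each = 20)
  bd <- c(rep("E12", 20), rep(c("E14", "E12"), 10), rep("E15", 20))
  expect_setequal(pick_late_clusters(cl, bd, n = 2), c(2L, 3L))
})
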