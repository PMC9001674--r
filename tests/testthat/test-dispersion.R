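test_that("dispersion summary matches hand computation", {
  d <- dispersion(c(0.2, 0.4))
  expect_equal(d$sd, sd(c(0.2, 0.4)))
  expect_equal(d$sd, 0.1414214, tolerance = 1e-6)
  expect_equal(d$iqr, 0.1)
  expect_equal(d$mean_pos, 0.3)
  expect_equal(d$iqr_mean_normalized, 1 / 3)

  dc <- dispersion(rep(0.5, 5))
  expect_equal(dc$sd, 0)
  expect_equal(dc$iqr, 0)
  expect_error(dispersion(0.3), "at least 2")
})

test_that("dispersion is translation invariant in spread, not location", {
  withr::local_seed(2)
  x <- runif(30, 0.2, 0.6)
  a <- dispersion(x); b <- dispersion(x + 0.2)
  expect_equal(b$sd, a$sd)
  expect_equal(b$iqr, a$iqr)
  expect_equal(b$mean_pos, a$mean_pos + 0.2)
})

test_that("mean-normalized density is a scale-invariant unit distribution", {
  withr::local_seed(3)
  x <- runif(200, 0.1, 0.9)
  d1 <- mean_normalized_density(x, n_bins = 20)
  expect_equal(sum(d1), 1, tolerance = 1e-12)
  d2 <- mean_normalized_density(x / 2, n_bins = 20)
  expect_equal(as.numeric(d1), as.numeric(d2))

  dd <- mean_normalized_density(rep(0.4, 10), n_bins = 20)
  expect_equal(sum(dd > 0), 1)
  expect_equal(max(dd), 1)
  mids <- attr(dd, "mids")
  expect_lt(abs(mids[which.max(dd)] - 1), 0.06)
  expect_error(mean_normalized_density(rep(0, 5)), "mean")
})

test_that("cohort clustering separates narrow from broad after centering", {
  withr::local_seed(11)
  ## two tight cohorts at different centers: same shape once centered
  tightA <- laminar_cohort(pmin(1, pmax(0, rnorm(150, 0.3, 0.05))))
  tightB <- laminar_cohort(pmin(1, pmax(0, rnorm(150, 0.7, 0.05))))
  broad <- lapply(1:3, function(i)
    laminar_cohort(pmin(1, pmax(0, rnorm(150, 0.4, 0.18)))))
  narrow <- lapply(1:3, function(i)
    laminar_cohort(pmin(1, pmax(0, rnorm(150, 0.75, 0.04)))))
  cl <- cluster_cohorts(c(list(tA = tightA, tB = tightB), stats::setNames(broad,
        paste0("broad", 1:3)), stats::setNames(narrow, paste0("narrow", 1:3))))
  labs <- cl$labels
  expect_equal(labs[["tA"]], labs[["tB"]])
  ## flat cut at 2 separates broad from narrow exactly
  expect_equal(length(unique(labs[paste0("broad", 1:3)])), 1)
  expect_equal(length(unique(labs[c(paste0("narrow", 1:3), "tA", "tB")])), 1)
  expect_false(labs[["broad1"]] == labs[["narrow1"]])

  dup <- cluster_cohorts(list(a = tightA, b = tightA, c = broad[[1]]))
  dm <- as.matrix(dist(dup$profiles))
  expect_equal(dm["a", "b"], 0)
  expect_error(cluster_cohorts(list(tightA, tightB), n_bins = 1), "n_bins")
})

test_that("Welch comparison matches the textbook formula", {
  a <- c(1, 2, 3); b <- c(1, 2, 3, 100)
  res <- compare_dispersion(a, b)
  ## independent hand evaluation of the Welch statistic and df
  se2 <- var(a) / length(a) + var(b) / length(b)
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 4)^2 / 3)
  expect_equal(res$statistic, t_hand)
  expect_equal(res$df, df_hand)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), df_hand))

  flip <- compare_dispersion(b, a)
  expect_equal(flip$statistic, -res$statistic)
  expect_equal(flip$p_value, res$p_value)

  same <- compare_dispersion(c(2, 2), c(2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)
})

test_that("KS comparison equals a brute-force ECDF sweep", {
  expect_equal(compare_distributions(c(0, 0, 0), c(1, 1, 1))$statistic, 1)
  expect_equal(compare_distributions(1:5, 1:5)$statistic, 0)
  withr::local_seed(9)
  for (i in 1:10) {
    a <- rnorm(20); b <- rnorm(20, 0.5)
    expect_equal(compare_distributions(a, b)$statistic, oracle_ks_stat(a, b))
  }
})

test_that("dispersion trend recovers slopes with honest confidence bands", {
  ## exact line: slope recovered with zero residual
  pts <- data.frame(collection_day = c(2, 4, 6, 8),
                    sd = 0.3 - 0.02 * c(2, 4, 6, 8),
                    cohort_label = "exact")
  fit <- suppressWarnings(dispersion_trend(pts))$exact  # zero-residual fit
  expect_equal(fit$slope, -0.02)
  expect_equal(fit$intercept, 0.3)
  expect_lt(max(abs(fit$band$fit - pts$sd)), 1e-12)

  ## point order is irrelevant
  fit2 <- suppressWarnings(dispersion_trend(pts[c(3, 1, 4, 2), ]))$exact
  expect_equal(fit2$slope, fit$slope)

  ## compacting late-born-like series vs flat early-born-like series
  withr::local_seed(13)
  days <- rep(2:9, each = 3)
  late <- data.frame(collection_day = days,
                     sd = 0.22 - 0.015 * days + rnorm(length(days), 0, 0.008),
                     cohort_label = "E15.5")
  early <- data.frame(collection_day = days,
                      sd = 0.16 + rnorm(length(days), 0, 0.01),
                      cohort_label = "E13.5")
  fits <- dispersion_trend(rbind(late, early))
  expect_lt(fits$E15.5$ci95_slope[2], 0)         # CI excludes 0, negative
  expect_lt(fits$E13.5$ci95_slope[1], 0)         # flat: CI straddles 0
  expect_gt(fits$E13.5$ci95_slope[2], 0)

  expect_error(dispersion_trend(data.frame(collection_day = c(3, 3, 3),
                                           sd = 1:3, cohort_label = "x")),
               "identical")
})
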