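#' An isochronic cohort of normalized radial positions
#'
#' @param positions Numeric vector of normalized depths in `[0, 1]`.
#' @param injection_age Embryonic day of the FlashTag pulse (e.g. `13.5`).
#' @param collection_age Collection day label (e.g. `"P7"` or a numeric day).
#' @param pup_id Animal identifier.
#' @return An object of class `laminar_cohort`.
#' @export
laminar_cohort <- function(positions, injection_age = NA, collection_age = NA,
                           pup_id = NA) {
  positions <- as.numeric(positions)
  check_finite(positions, "positions")
  if (length(positions) && (min(positions) < 0 || max(positions) > 1))
    stop("positions must lie in [0, 1]", call. = FALSE)
  structure(list(positions = positions, injection_age = injection_age,
                 collection_age = collection_age, pup_id = pup_id),
            class = "laminar_cohort")
}

#' Dispersion summary of a cohort's radial positions
#'
#' @param cohort A [laminar_cohort()] or numeric position vector with at
#'   least two values.
#' @return A one-row `data.frame`: `n`, `mean_pos`, `sd` (sample standard
#'   deviation, `n - 1` denominator), `iqr` (Q3 - Q1, interpolated
#'   quantiles) and `iqr_mean_normalized` (`iqr / mean_pos`).
#' @export
dispersion <- function(cohort) {
  x <- if (inherits(cohort, "laminar_cohort")) cohort$positions else as.numeric(cohort)
  if (length(x) < 2) stop("dispersion needs at least 2 positions", call. = FALSE)
  q <- interp_quantile(x, c(0.25, 0.75))
  m <- mean(x)
  data.frame(n = length(x), mean_pos = m, sd = stats::sd(x),
             iqr = q[2] - q[1],
             iqr_mean_normalized = if (m == 0) NA_real_ else (q[2] - q[1]) / m)
}

#' Density of radial positions normalized to the cohort mean
#'
#' Divides positions by the cohort (per-pup) mean, histograms the rescaled
#' values into `n_bins` equal bins over a fixed range, and normalizes the
#' result to sum to 1.  By construction the output is invariant to a
#' uniform rescaling of the raw positions.
#'
#' @param cohort A [laminar_cohort()] or numeric vector.
#' @param n_bins Number of bins (default 20).
#' @param range Fixed range of mean-normalized position covered by the
#'   histogram; values outside are clamped to the end bins.
#' @return Numeric density vector of length `n_bins` summing to 1, with the
#'   bin midpoints in attribute `mids`.
#' @export
mean_normalized_density <- function(cohort, n_bins = 20, range = c(0, 2)) {
  x <- if (inherits(cohort, "laminar_cohort")) cohort$positions else as.numeric(cohort)
  if (length(x) == 0) stop("cohort is empty", call. = FALSE)
  m <- mean(x)
  if (m == 0) stop("cohort mean is zero; cannot mean-normalize", call. = FALSE)
  binned_density(x / m, n_bins, range)
}

## histogram over a fixed range, clamped, normalized to sum 1
binned_density <- function(x, n_bins, range) {
  stopifnot(n_bins >= 2)
  breaks <- seq(range[1], range[2], length.out = n_bins + 1)
  x <- pmin(pmax(x, range[1]), range[2])
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  d <- counts / sum(counts)
  attr(d, "mids") <- (breaks[-1] + breaks[-length(breaks)]) / 2
  d
}

#' Hierarchical clustering of cohorts by centered radial distribution
#'
#' Represents each cohort as the binned density of its mean-centered
#' positions (positions minus the cohort mean, over a fixed symmetric
#' range), computes pairwise Euclidean distances between these profiles,
#' and clusters agglomeratively.  Centering removes laminar location, so
#' the clustering is driven purely by the shape/spread of the
#' distribution — broad early cohorts separate from compact late ones.
#'
#' @param cohorts Named list of [laminar_cohort()] objects (>= 2).
#' @param n_bins Bins of the centered-density profile (default 20).
#' @param range Symmetric centered-depth range of the profile.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param k Number of flat clusters cut from the tree (default 2,
#'   mirroring an early/late bipartition).
#' @return List with `hclust` (the dendrogram), `labels` (named integer
#'   flat-cut assignments) and `profiles` (cohort x bin matrix).
#' @export
cluster_cohorts <- function(cohorts, n_bins = 20, range = c(-0.5, 0.5),
                            linkage = "average", k = 2) {
  stopifnot(length(cohorts) >= 2, n_bins >= 2)
  nm <- names(cohorts) %||% paste0("cohort", seq_along(cohorts))
  profiles <- t(vapply(cohorts, function(cc) {
    x <- if (inherits(cc, "laminar_cohort")) cc$positions else as.numeric(cc)
    as.numeric(binned_density(x - mean(x), n_bins, range))
  }, numeric(n_bins)))
  rownames(profiles) <- nm
  hc <- stats::hclust(stats::dist(profiles, method = "euclidean"),
                      method = linkage)
  list(hclust = hc, labels = stats::cutree(hc, k = min(k, length(cohorts))),
       profiles = profiles)
}

#' Welch test between two groups of dispersion values
#'
#' Two-sample unequal-variance (Welch) t test on per-cohort standard
#' deviations, e.g. early-injected versus late-injected brains.
#'
#' @param group_a,group_b Numeric vectors of dispersion values (typically
#'   the `sd` column of [dispersion()] summaries), each of length >= 2.
#' @return List with `statistic`, `df` (Welch-Satterthwaite) and `p_value`
#'   (two-sided).  If both groups are constant and equal, the statistic is
#'   0 and `p_value` 1 with `degenerate = TRUE`.
#' @export
compare_dispersion <- function(group_a, group_b) {
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(statistic = 0, df = NA_real_, p_value = 1, degenerate = TRUE))
    return(list(statistic = sign(mean(group_a) - mean(group_b)) * Inf,
                df = NA_real_, p_value = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, degenerate = FALSE)
}

#' Two-sample Kolmogorov-Smirnov comparison of position distributions
#'
#' @param a,b Non-empty numeric vectors of positions.
#' @return List with `statistic` (max absolute ECDF difference) and
#'   `p_value` (two-sided).
#' @export
compare_distributions <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  ks <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided"))
  list(statistic = unname(ks$statistic), p_value = ks$p.value)
}

#' Linear trend of radial dispersion over collection time
#'
#' Ordinary least-squares fit of per-cohort standard deviation on
#' collection day, per cohort label (e.g. one fit for E13.5-born and one
#' for E15.5-born series), with the 95% confidence interval of the slope
#' and of the mean-response band.
#'
#' @param points `data.frame` with columns `collection_day` (numeric),
#'   `sd` and `cohort_label`; >= 3 points per label.
#' @return Named list per label: `slope`, `intercept`, `ci95_slope`
#'   (length-2), and `band` (`data.frame`: `collection_day`, `fit`, `lwr`,
#'   `upr`).
#' @export
dispersion_trend <- function(points) {
  stopifnot(all(c("collection_day", "sd", "cohort_label") %in% names(points)))
  out <- lapply(split(points, points$cohort_label), function(df) {
    if (nrow(df) < 3) stop("need >= 3 points per label", call. = FALSE)
    if (length(unique(df$collection_day)) < 2)
      stop("all collection days identical; no slope estimable", call. = FALSE)
    fit <- stats::lm(sd ~ collection_day, data = df)
    ci <- stats::confint(fit, "collection_day", level = 0.95)
    pred <- stats::predict(fit, interval = "confidence", level = 0.95)
    list(slope = unname(stats::coef(fit)["collection_day"]),
         intercept = unname(stats::coef(fit)["(Intercept)"]),
         ci95_slope = as.numeric(ci),
         band = data.frame(collection_day = df$collection_day,
                           fit = pred[, "fit"], lwr = pred[, "lwr"],
                           upr = pred[, "upr"]))
  })
  out
}
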