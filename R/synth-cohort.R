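#' Specification of a simulated isochronic neuron cohort
#'
#' Describes one imaging section worth of FlashTag/BrdU-labelled cells: a
#' cohort of neurons whose true normalized radial depths follow a truncated
#' normal with a cohort-specific center and spread, a fraction of which are
#' directly progenitor-born (high FlashTag, no BrdU incorporation).
#' Intensities are log-normal: imaging intensities are non-negative and
#' right-skewed, so the high/low parameters are location and scale on the
#' log scale.
#'
#' @param n_cells Number of cells to simulate.
#' @param center True mean normalized depth in `[0, 1]` (0 = subplate lower
#'   border, 1 = pial surface).
#' @param spread_sd True standard deviation of depth, same units.
#' @param frac_direct_born Fraction of cells that are directly born (bright
#'   FlashTag, BrdU negative).
#' @param ft_hi,ft_lo Length-2 numeric `(meanlog, sdlog)` of the FlashTag
#'   intensity distribution for direct-born vs. dye-diluted cells.
#' @param brdu_hi,brdu_lo Same for BrdU intensity of incorporating vs.
#'   non-incorporating cells.
#' @param section_width,section_height Section extent in pixels.
#' @param landmark_jitter Vertical jitter (pixels) applied to the landmark
#'   polyline vertices, emulating curved pia/subplate borders.
#' @param seed Integer seed; all output is a pure function of the spec.
#' @return An object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_cells = 300,
                            center = 0.5,
                            spread_sd = 0.1,
                            frac_direct_born = 0.15,
                            ft_hi = c(6, 0.3), ft_lo = c(4, 0.3),
                            brdu_hi = c(6, 0.3), brdu_lo = c(2, 0.3),
                            section_width = 1000, section_height = 800,
                            landmark_jitter = 10,
                            seed = 1L) {
  spec <- list(n_cells = n_cells, center = center, spread_sd = spread_sd,
               frac_direct_born = frac_direct_born,
               ft_hi = ft_hi, ft_lo = ft_lo,
               brdu_hi = brdu_hi, brdu_lo = brdu_lo,
               section_width = section_width, section_height = section_height,
               landmark_jitter = landmark_jitter, seed = as.integer(seed))
  for (f in c("n_cells", "center", "spread_sd", "frac_direct_born", "ft_hi",
              "ft_lo", "brdu_hi", "brdu_lo", "section_width", "section_height",
              "landmark_jitter", "seed")) {
    check_finite(spec[[f]], f)
  }
  stopifnot(spec$n_cells >= 0, spec$spread_sd >= 0,
            spec$frac_direct_born >= 0, spec$frac_direct_born <= 1,
            spec$center >= 0, spec$center <= 1)
  if (spec$ft_hi[1] <= spec$ft_lo[1])
    stop("ft_hi location must exceed ft_lo location", call. = FALSE)
  if (spec$brdu_hi[1] <= spec$brdu_lo[1])
    stop("brdu_hi location must exceed brdu_lo location", call. = FALSE)
  structure(spec, class = "cohort_sim_spec")
}

#' Simulate a detected-cell table for one isochronic cohort
#'
#' Draws true normalized depths from `Normal(center, spread_sd)` truncated
#' (clamped) to `[0, 1]`, places each cell between two jittered landmark
#' polylines (subplate lower border at the bottom, pia at the top) at a
#' uniform lateral position, and draws log-normal FlashTag / BrdU
#' intensities conditional on the direct-born flag.  Deterministic given
#' the spec seed.
#'
#' @param spec A [cohort_sim_spec()].
#' @param section_id Identifier written into the cell and landmark tables.
#' @return A list with
#'   `cells` (`data.frame`: `section_id, x, y, ft_intensity, brdu_intensity,
#'   size`), `geometry` (a `section_geometry`), and
#'   `truth` (`data.frame`: `true_depth`, logical `direct_born`).
#' @export
simulate_cohort <- function(spec, section_id = "s1") {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  with_seed(spec$seed, {
    w <- spec$section_width; h <- spec$section_height
    nx <- 6L
    xs <- seq(0, w, length.out = nx)
    jit <- spec$landmark_jitter
    y_sub <- 0.1 * h + stats::rnorm(nx, 0, jit)
    y_pia <- 0.9 * h + stats::rnorm(nx, 0, jit)
    geom <- section_geometry(
      section_id = section_id,
      pia = cbind(x = xs, y = y_pia),
      subplate = cbind(x = xs, y = y_sub)
    )

    n <- spec$n_cells
    if (n == 0L) {
      empty <- data.frame(section_id = character(0), x = numeric(0),
                          y = numeric(0), ft_intensity = numeric(0),
                          brdu_intensity = numeric(0), size = numeric(0))
      return(list(cells = empty, geometry = geom,
                  truth = data.frame(true_depth = numeric(0),
                                     direct_born = logical(0))))
    }

    depth <- pmin(1, pmax(0, stats::rnorm(n, spec$center, spec$spread_sd)))
    x <- stats::runif(n, 0.02 * w, 0.98 * w)
    ## linear interpolation of both landmark polylines at the cell's x
    ys <- stats::approx(xs, y_sub, xout = x)$y
    yp <- stats::approx(xs, y_pia, xout = x)$y
    y <- ys + depth * (yp - ys)

    direct <- stats::runif(n) < spec$frac_direct_born
    ft <- stats::rlnorm(n, ifelse(direct, spec$ft_hi[1], spec$ft_lo[1]),
                        ifelse(direct, spec$ft_hi[2], spec$ft_lo[2]))
    ## direct-born cells never pass through an intercurrent S phase, so they
    ## do not incorporate chronically delivered BrdU
    brdu <- stats::rlnorm(n, ifelse(direct, spec$brdu_lo[1], spec$brdu_hi[1]),
                          ifelse(direct, spec$brdu_lo[2], spec$brdu_hi[2]))
    cells <- data.frame(
      section_id = section_id, x = x, y = y,
      ft_intensity = ft, brdu_intensity = brdu,
      size = stats::rlnorm(n, log(80), 0.25)
    )
    list(cells = cells, geometry = geom,
         truth = data.frame(true_depth = depth, direct_born = direct))
  })
}
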