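#' Gate directly progenitor-born (FT+ BrdU-) cells
#'
#' Per section, keeps cells whose FlashTag intensity is strictly above that
#' section's median FlashTag intensity and whose BrdU intensity is strictly
#' below the section's 20th percentile of BrdU intensity.  High FlashTag
#' selects cells that did not dilute the dye by division; low BrdU selects
#' cells that did not pass through an intercurrent S phase under chronic
#' BrdU delivery — together, the directly apical-progenitor-born neurons.
#'
#' Percentiles use linear interpolation between order statistics; the
#' median comparison is strict, so ties at the median are excluded.
#'
#' @param cells `data.frame` of detected cells with columns `section_id`,
#'   `ft_intensity`, `brdu_intensity`.
#' @param brdu_pct BrdU percentile defining "BrdU negative" (default 0.20).
#' @return A list with `kept` (the gated subset of `cells`) and `report`
#'   (`data.frame` per section: `section_id`, `n_total`, `n_kept`,
#'   `ft_median`, `brdu_cutoff`).  Sections where all FlashTag intensities
#'   are equal keep zero cells and raise a warning (median rule degenerate).
#' @export
gate_direct_born <- function(cells, brdu_pct = 0.20) {
  need <- c("section_id", "ft_intensity", "brdu_intensity")
  stopifnot(all(need %in% names(cells)))
  check_finite(cells$ft_intensity, "ft_intensity")
  check_finite(cells$brdu_intensity, "brdu_intensity")
  if (any(cells$ft_intensity < 0) || any(cells$brdu_intensity < 0))
    stop("intensities must be >= 0", call. = FALSE)
  if (nrow(cells) == 0) {
    return(list(kept = cells,
                report = data.frame(section_id = character(0),
                                    n_total = integer(0), n_kept = integer(0),
                                    ft_median = numeric(0),
                                    brdu_cutoff = numeric(0))))
  }
  secs <- split(seq_len(nrow(cells)), cells$section_id)
  keep <- logical(nrow(cells))
  report <- lapply(names(secs), function(s) {
    idx <- secs[[s]]
    ft <- cells$ft_intensity[idx]
    brdu <- cells$brdu_intensity[idx]
    ft_med <- stats::median(ft)
    brdu_cut <- interp_quantile(brdu, brdu_pct)
    pass <- ft > ft_med & brdu < brdu_cut
    if (all(ft == ft[1]))
      warning("section '", s, "': all FlashTag intensities equal; ",
              "median gate keeps no cells", call. = FALSE)
    keep[idx] <<- pass
    data.frame(section_id = s, n_total = length(idx), n_kept = sum(pass),
               ft_median = ft_med, brdu_cutoff = brdu_cut,
               stringsAsFactors = FALSE)
  })
  list(kept = cells[keep, , drop = FALSE],
       report = do.call(rbind, report))
}

#' Gate the brightest FlashTag cells
#'
#' Per section, keeps cells whose FlashTag intensity is at or above the
#' `(1 - fraction)` quantile of the section (top-`fraction` brightest
#' cells; ties at the boundary are all kept).  Used as an alternative
#' direct-born gate when no chronic BrdU channel is available.
#'
#' @param cells `data.frame` with `section_id` and `ft_intensity`.
#' @param fraction Top fraction to keep, in `(0, 1]`; default 0.10.
#' @return The subset of `cells` passing the gate.
#' @export
gate_top_ft <- function(cells, fraction = 0.10) {
  stopifnot(all(c("section_id", "ft_intensity") %in% names(cells)))
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  if (nrow(cells) == 0) return(cells)
  keep <- unlist(lapply(split(seq_len(nrow(cells)), cells$section_id),
                        function(idx) {
    cut <- interp_quantile(cells$ft_intensity[idx], 1 - fraction)
    idx[cells$ft_intensity[idx] >= cut]
  }), use.names = FALSE)
  cells[sort(keep), , drop = FALSE]
}
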