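#' Landmark geometry of one imaged section
#'
#' Holds the manually traced landmark polylines of a cortical section: the
#' pial surface and the lower border of the subplate, plus optionally the
#' upper and lower limits of the cortical plate.  Polylines are two-column
#' matrices of `(x, y)` pixel coordinates with at least two vertices.
#'
#' @param section_id Identifier.
#' @param pia,subplate Polylines (`n x 2` matrices, ordered vertices).
#' @param cp_upper,cp_lower Optional cortical-plate limit polylines.
#' @return An object of class `section_geometry`.
#' @export
section_geometry <- function(section_id, pia, subplate,
                             cp_upper = NULL, cp_lower = NULL) {
  as_poly <- function(p, name) {
    if (is.null(p)) return(NULL)
    p <- as.matrix(p)
    if (ncol(p) != 2 || nrow(p) < 2)
      stop("polyline '", name, "' needs >= 2 (x, y) points", call. = FALSE)
    check_finite(p, name)
    storage.mode(p) <- "double"
    colnames(p) <- c("x", "y")
    p
  }
  structure(list(section_id = section_id,
                 pia = as_poly(pia, "pia"),
                 subplate = as_poly(subplate, "subplate"),
                 cp_upper = as_poly(cp_upper, "cp_upper"),
                 cp_lower = as_poly(cp_lower, "cp_lower")),
            class = "section_geometry")
}

## Euclidean distance from each point (px, py) to the nearest point of a
## polyline, using exact point-to-segment projection.
point_polyline_distance <- function(px, py, poly) {
  n <- nrow(poly)
  best <- rep(Inf, length(px))
  for (i in seq_len(n - 1)) {
    ax <- poly[i, 1]; ay <- poly[i, 2]
    bx <- poly[i + 1, 1]; by <- poly[i + 1, 2]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
    d2 <- (px - (ax + t * dx))^2 + (py - (ay + t * dy))^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Normalized radial position of cells within a section
#'
#' Computes, for each cell, the normalized depth
#' `r = d_sub / (d_sub + d_pia)` where `d_sub` and `d_pia` are the
#' Euclidean distances to the nearest point of the subplate-lower-border
#' and pial-surface polylines.  `r = 0` on the subplate lower border and
#' `r = 1` on the pia.  Distances use exact nearest-point-on-segment
#' projection, so the result is invariant under rigid motions of the
#' section coordinates.
#'
#' @param cells `data.frame` with `x`, `y` columns (one row per cell).
#' @param geom A [section_geometry()].
#' @return Numeric vector of depths in `[0, 1]`.
#' @export
radial_position <- function(cells, geom) {
  stopifnot(inherits(geom, "section_geometry"))
  if (nrow(cells) == 0) return(numeric(0))
  d_sub <- point_polyline_distance(cells$x, cells$y, geom$subplate)
  d_pia <- point_polyline_distance(cells$x, cells$y, geom$pia)
  tot <- d_sub + d_pia
  r <- ifelse(tot == 0, 0.5, d_sub / tot)
  r
}

#' Normalize cohort positions to cortex or cortical-plate thickness
#'
#' In `"cortex"` mode positions are the depths of [radial_position()]
#' (already normalized to full cortical thickness across animals).  In
#' `"cortical_plate"` mode depths are rescaled so that the cortical-plate
#' lower and upper limits map to 0 and 1; cells falling outside `[0, 1]`
#' after rescaling are outside the cortical plate and are excluded (their
#' count is reported in attribute `n_excluded`).
#'
#' @param positions Numeric vector of cortex-normalized depths in `[0, 1]`.
#' @param mode `"cortex"` or `"cortical_plate"`.
#' @param geom A [section_geometry()]; `cp_upper` / `cp_lower` required in
#'   cortical-plate mode.  The CP limits are converted to cortex depth via
#'   [radial_position()] of their vertices.
#' @return Numeric vector of normalized depths with attribute `n_excluded`.
#' @export
normalize_positions <- function(positions, mode = c("cortex", "cortical_plate"),
                                geom = NULL) {
  mode <- match.arg(mode)
  if (mode == "cortex") {
    out <- positions
    attr(out, "n_excluded") <- 0L
    return(out)
  }
  if (is.null(geom) || is.null(geom$cp_upper) || is.null(geom$cp_lower))
    stop("cortical_plate mode requires cp_upper and cp_lower landmarks",
         call. = FALSE)
  depth_of <- function(poly) {
    mean(radial_position(data.frame(x = poly[, 1], y = poly[, 2]), geom))
  }
  lo <- depth_of(geom$cp_lower)
  hi <- depth_of(geom$cp_upper)
  if (hi <= lo) stop("cp_upper must lie above cp_lower", call. = FALSE)
  r <- (positions - lo) / (hi - lo)
  keep <- r >= 0 & r <= 1
  out <- r[keep]
  attr(out, "n_excluded") <- sum(!keep)
  out
}
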