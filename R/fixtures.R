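#' Canonical simulated expression study design
#'
#' The expression simulation mirroring the structure of the birthdated
#' single-cell resource analysed by the heterogeneity statistic: four
#' birthdates (E12-E15) at three stages (apical progenitor, 1-day-old and
#' 4-day-old neurons) plus adult deep-layer and superficial-layer neurons.
#' Latent structure encodes the biology the statistic should detect:
#' apical progenitors are homogeneous (one program); 1-day-old early-born
#' neurons carry three strong partially-executed programs; 4-day-old
#' early-born neurons retain two weaker ones; late-born neurons are
#' homogeneous at both neuronal stages; adult deep-layer neurons carry
#' three subtype programs, superficial-layer neurons one.
#'
#' @param seed Integer seed.
#' @param n_genes Genes simulated (default 1000).
#' @param cells_per_condition Cells per condition (default 150).
#' @return An [expr_sim_spec()].
#' @export
fixture_expr_spec <- function(seed = 1L, n_genes = 1000,
                              cells_per_condition = 150) {
  n <- cells_per_condition
  cond <- function(label, k, logfc) {
    sim_condition(label = label, n_cells = n, k_subtypes = k,
                  effect_logfc = logfc, program_size = 40,
                  nb_dispersion = 0.5, dropout_rate = 0.1)
  }
  conditions <- c(
    lapply(c("E12", "E13", "E14", "E15"),
           function(b) cond(paste0(b, "_AP"), 1, 0)),
    lapply(c("E12", "E13"), function(b) cond(paste0(b, "_N1d"), 3, 2)),
    lapply(c("E14", "E15"), function(b) cond(paste0(b, "_N1d"), 1, 0)),
    lapply(c("E12", "E13"), function(b) cond(paste0(b, "_N4d"), 2, 1)),
    lapply(c("E14", "E15"), function(b) cond(paste0(b, "_N4d"), 1, 0)),
    list(cond("adult_DL", 3, 2), cond("adult_SL", 1, 0))
  )
  expr_sim_spec(n_genes = n_genes, mito_gene_frac = 0.02,
                conditions = conditions, seed = seed)
}

#' Canonical simulated imaging study design
#'
#' Three pups per injection age, two injection ages: an early cohort
#' (broadly dispersed across deep layers) and a late cohort (laminarly
#' compact, superficial).  Centers and spreads follow the qualitative
#' contrast between early- and late-born laminar distributions.
#'
#' @param seed Integer seed.
#' @param n_cells Cells per section (default 300).
#' @return `data.frame` of per-section specs with columns `pup_id`,
#'   `injection_age`, `collection_age`, `section_id`, `center`,
#'   `spread_sd`, `seed`.
#' @export
fixture_imaging_design <- function(seed = 1L, n_cells = 300) {
  design <- expand.grid(pup = 1:3, injection_age = c(13.5, 15.5))
  seeds <- fan_out_seeds(seed, nrow(design))
  data.frame(
    pup_id = paste0("p", design$pup),
    injection_age = design$injection_age,
    collection_age = "P7",
    section_id = sprintf("E%s_p%d", design$injection_age, design$pup),
    center = ifelse(design$injection_age < 14.5, 0.35, 0.75),
    spread_sd = ifelse(design$injection_age < 14.5, 0.15, 0.05),
    n_cells = n_cells,
    seed = seeds,
    stringsAsFactors = FALSE
  )
}

#' Write the standard synthetic fixtures to disk
#'
#' Writes one imaging fixture (3 pups x 2 injection-age cohorts: cells.csv,
#' landmarks.csv, cohorts.csv, truth.csv under `imaging/`) and one
#' expression fixture ([fixture_expr_spec()] conditions, Matrix Market plus
#' TSV metadata under `expr/`).  Byte-identical across runs with the same
#' seed.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory, created if needed.
#' @param n_genes,cells_per_condition,n_cells_imaging Size knobs passed to
#'   the fixture specs.
#' @return Invisibly, a list of the written paths.
#' @export
make_fixtures <- function(seed, out_dir, n_genes = 1000,
                          cells_per_condition = 150, n_cells_imaging = 300) {
  img_dir <- file.path(out_dir, "imaging")
  expr_dir <- file.path(out_dir, "expr")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)

  design <- fixture_imaging_design(seed, n_cells = n_cells_imaging)
  cells <- list(); landmarks <- list(); truth <- list()
  for (i in seq_len(nrow(design))) {
    spec <- cohort_sim_spec(n_cells = design$n_cells[i],
                            center = design$center[i],
                            spread_sd = design$spread_sd[i],
                            seed = design$seed[i])
    sim <- simulate_cohort(spec, section_id = design$section_id[i])
    cells[[i]] <- sim$cells
    landmarks[[i]] <- geometry_to_table(sim$geometry)
    truth[[i]] <- cbind(section_id = design$section_id[i], sim$truth)
  }
  wr <- function(df, path) {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    path
  }
  paths <- list(
    cells = wr(do.call(rbind, cells), file.path(img_dir, "cells.csv")),
    landmarks = wr(do.call(rbind, landmarks), file.path(img_dir, "landmarks.csv")),
    cohorts = wr(design[, c("section_id", "injection_age", "collection_age",
                            "pup_id")],
                 file.path(img_dir, "cohorts.csv")),
    truth = wr(do.call(rbind, truth), file.path(img_dir, "truth.csv"))
  )
  espec <- fixture_expr_spec(seed, n_genes = n_genes,
                             cells_per_condition = cells_per_condition)
  cm <- simulate_counts(espec)
  paths$expr <- write_count_matrix(cm, expr_dir)
  invisible(paths)
}

geometry_to_table <- function(geom) {
  one <- function(poly, structure) {
    if (is.null(poly)) return(NULL)
    data.frame(section_id = geom$section_id, structure = structure,
               point_index = seq_len(nrow(poly)),
               x = poly[, 1], y = poly[, 2], stringsAsFactors = FALSE)
  }
  do.call(rbind, Filter(Negate(is.null), list(
    one(geom$pia, "pia"), one(geom$subplate, "subplate"),
    one(geom$cp_upper, "cp_upper"), one(geom$cp_lower, "cp_lower"))))
}

#' Read a landmarks table back into section geometries
#'
#' @param landmarks `data.frame` with columns `section_id`, `structure`
#'   (`pia`, `subplate`, `cp_upper`, `cp_lower`), `point_index`, `x`, `y`,
#'   e.g. read from a `landmarks.csv`.
#' @return Named list of [section_geometry()] objects, one per section.
#' @export
geometries_from_table <- function(landmarks) {
  secs <- split(landmarks, landmarks$section_id)
  lapply(secs, function(df) {
    poly <- function(st) {
      sub <- df[df$structure == st, ]
      if (nrow(sub) == 0) return(NULL)
      sub <- sub[order(sub$point_index), ]
      cbind(x = sub$x, y = sub$y)
    }
    section_geometry(df$section_id[1], pia = poly("pia"),
                     subplate = poly("subplate"),
                     cp_upper = poly("cp_upper"), cp_lower = poly("cp_lower"))
  })
}

#' Read the imaging fixture written by [make_fixtures()]
#'
#' @param dir The `imaging/` directory.
#' @return List with `cells`, `geometries` (per section), `cohorts` and
#'   (if present) `truth`.
#' @export
read_imaging_fixture <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  out <- list(cells = rd("cells.csv"),
              geometries = geometries_from_table(rd("landmarks.csv")),
              cohorts = rd("cohorts.csv"))
  tf <- file.path(dir, "truth.csv")
  if (file.exists(tf)) out$truth <- utils::read.csv(tf, stringsAsFactors = FALSE)
  out
}
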