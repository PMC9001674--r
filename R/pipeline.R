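#' Run the full analysis pipeline on fixture or user data
#'
#' Orchestrates the stages in dependency order — synthetic-data generation
#' (optional), direct-born gating and radial-dispersion statistics,
#' single-cell QC/normalization, the heterogeneity statistic per condition,
#' and clustering with birthdate composition — writing one tidy CSV per
#' stage plus a JSON run manifest recording parameters, seeds and output
#' file hashes.
#'
#' @param config Named list (or path to a YAML file) with keys:
#'   `seed` (master seed), `out_dir`, optional `simulate` (logical; default
#'   `TRUE` generates fixtures under `out_dir/fixtures`), optional
#'   `imaging_dir` / `expr_dir` (inputs when `simulate` is `FALSE`),
#'   optional `stages` (subset of `c("ftquant", "qc", "hetero",
#'   "cluster")`), and the stage parameter groups `ftquant` (`bins`),
#'   `qc` (`min_genes`, `max_mito`, `min_count`, `min_cells`), `hetero`
#'   (`n_cells`, `k_genes`, `n_reps`, `conditions`), `cluster`
#'   (`n_var_genes`, `dims`, `resolution`, `k_neighbors`, `condition`).
#'   Unknown top-level keys are rejected before any computation.
#' @return Invisibly, the manifest list (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "out_dir", "simulate", "imaging_dir", "expr_dir",
             "stages", "ftquant", "qc", "hetero", "cluster", "fixture")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% stop("config needs out_dir", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% c("ftquant", "qc", "hetero", "cluster")
  stage_seeds <- fan_out_seeds(seed, 4)
  manifest <- list(config = config, seed = seed,
                   stage_seeds = as.list(stats::setNames(
                     stage_seeds, c("simulate", "ftquant", "hetero", "cluster"))),
                   outputs = list())
  written <- character(0)

  if (isTRUE(config$simulate %||% TRUE)) {
    fx <- config$fixture %||% list()
    fdir <- file.path(out_dir, "fixtures")
    make_fixtures(stage_seeds[1], fdir,
                  n_genes = fx$n_genes %||% 1000,
                  cells_per_condition = fx$cells_per_condition %||% 150,
                  n_cells_imaging = fx$n_cells_imaging %||% 300)
    imaging_dir <- file.path(fdir, "imaging")
    expr_dir <- file.path(fdir, "expr")
  } else {
    imaging_dir <- config$imaging_dir
    expr_dir <- config$expr_dir
  }

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  if ("ftquant" %in% stages && !is.null(imaging_dir)) {
    run_stage("ftquant", function() {
      img <- read_imaging_fixture(imaging_dir)
      gated <- gate_direct_born(img$cells)
      pos <- do.call(rbind, lapply(split(gated$kept, gated$kept$section_id),
        function(df) {
          geom <- img$geometries[[df$section_id[1]]]
          data.frame(section_id = df$section_id,
                     radial_position = radial_position(df, geom))
        }))
      rownames(pos) <- NULL
      pos <- merge(pos, img$cohorts, by = "section_id")
      disp <- do.call(rbind, lapply(split(pos, pos$section_id), function(df) {
        cbind(df[1, c("section_id", "injection_age", "pup_id")],
              dispersion(df$radial_position))
      }))
      rownames(disp) <- NULL
      utils::write.csv(gated$kept, file.path(out_dir, "gated_cells.csv"),
                       row.names = FALSE)
      utils::write.csv(pos, file.path(out_dir, "positions.csv"),
                       row.names = FALSE)
      utils::write.csv(disp, file.path(out_dir, "dispersion.csv"),
                       row.names = FALSE)
      cohorts <- lapply(split(pos, pos$section_id),
                        function(df) laminar_cohort(df$radial_position))
      cl <- cluster_cohorts(cohorts, n_bins = config$ftquant$bins %||% 20)
      jsonlite::write_json(
        list(merge_order = apply(cl$hclust$merge, 1, as.list),
             heights = cl$hclust$height, labels = cl$hclust$labels,
             flat_k2 = as.list(cl$labels)),
        file.path(out_dir, "clustering.json"), auto_unbox = TRUE)
      written <<- c(written, "gated_cells.csv", "positions.csv",
                    "dispersion.csv", "clustering.json")
    })
  }

  cm_norm <- NULL; cm_filtered <- NULL
  if (any(c("qc", "hetero", "cluster") %in% stages) && !is.null(expr_dir)) {
    run_stage("qc", function() {
      cm <- read_count_matrix(expr_dir)
      qc <- qc_filter(cm, min_genes = config$qc$min_genes %||% 2000,
                      max_mito = config$qc$max_mito %||% 0.12)
      ## simulated matrices are far shallower than real libraries; keep the
      ## gene-breadth filter proportionate when configured
      cm_filtered <<- filter_genes(qc$kept,
                                   min_count = config$qc$min_count %||% 100,
                                   min_cells = config$qc$min_cells %||% 2)
      cm_norm <<- rpm_log2(cm_filtered)
      utils::write.csv(qc$report, file.path(out_dir, "qc_report.csv"),
                       row.names = FALSE)
      written <<- c(written, "qc_report.csv")
    })
  }

  if ("hetero" %in% stages && !is.null(cm_filtered)) {
    run_stage("hetero", function() {
      hp <- config$hetero %||% list()
      conds <- hp$conditions %||% unique(cm_filtered$cell_meta$condition)
      n_cells <- hp$n_cells %||% 80
      conds <- conds[table(cm_filtered$cell_meta$condition)[conds] >= n_cells]
      rseeds <- fan_out_seeds(stage_seeds[3], length(conds))
      runs <- lapply(seq_along(conds), function(i)
        heterogeneity_ratio(cm_filtered, conds[i],
                            n_cells = n_cells,
                            k_genes = hp$k_genes %||% 80,
                            n_reps = hp$n_reps %||% 100,
                            seed = rseeds[i]))
      long <- do.call(rbind, lapply(runs, function(r)
        cbind(condition = r$condition, r$reps)))
      utils::write.csv(long, file.path(out_dir, "hetero_runs.csv"),
                       row.names = FALSE)
      cmp <- compare_heterogeneity(runs, dl_conditions = "adult_DL",
                                   sl_conditions = "adult_SL")
      utils::write.csv(cmp$summary, file.path(out_dir, "hetero_summary.csv"),
                       row.names = FALSE)
      written <<- c(written, "hetero_runs.csv", "hetero_summary.csv")
    })
  }

  if ("cluster" %in% stages && !is.null(cm_filtered)) {
    run_stage("cluster", function() {
      cp <- config$cluster %||% list()
      target_stage <- cp$condition %||% "N1d"
      sel <- which(cm_filtered$cell_meta$stage == target_stage)
      sub <- subset_cm(cm_filtered, cells = sel)
      asg <- cluster_neurons(sub,
                             n_var_genes = cp$n_var_genes %||% 2000,
                             dims = cp$dims %||% 15,
                             resolution = cp$resolution %||% 1.0,
                             k_neighbors = cp$k_neighbors %||% 20,
                             seed = stage_seeds[4])
      comp <- composition(asg, sub$cell_meta$birthdate)
      utils::write.csv(data.frame(cell_id = names(asg$cluster),
                                  cluster = asg$cluster),
                       file.path(out_dir, "clusters.csv"), row.names = FALSE)
      comp_df <- as.data.frame(as.table(comp$fractions))
      names(comp_df) <- c("cluster", "birthdate", "fraction")
      utils::write.csv(comp_df, file.path(out_dir, "composition.csv"),
                       row.names = FALSE)
      written <<- c(written, "clusters.csv", "composition.csv")
    })
  }

  manifest$outputs <- lapply(stats::setNames(written, written), function(f)
    unname(tools::md5sum(file.path(out_dir, f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(manifest)
}

#' Consolidated report over a completed pipeline run
#'
#' Gathers the stage outputs of [run_pipeline()] into tidy tables and a
#' short text summary of sanity checks (e.g. whether homogeneous
#' conditions calibrate to a mean heterogeneity ratio near 1).  Missing
#' stage outputs are skipped with a notice.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return List of tables (`dispersion`, `hetero`, `hetero_summary`,
#'   `composition`) plus `notes` (character) — also written to
#'   `run_dir/report.txt`.
#' @export
report <- function(run_dir) {
  out <- list(notes = character(0))
  grab <- function(f) {
    p <- file.path(run_dir, f)
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE) else {
      out$notes <<- c(out$notes, paste0("missing stage output: ", f))
      NULL
    }
  }
  out$dispersion <- grab("dispersion.csv")
  out$hetero <- grab("hetero_runs.csv")
  out$hetero_summary <- grab("hetero_summary.csv")
  out$composition <- grab("composition.csv")
  if (!is.null(out$hetero_summary)) {
    homog <- out$hetero_summary[grepl("_AP$|adult_SL", out$hetero_summary$condition), ]
    if (nrow(homog)) {
      ok <- homog$mean_ratio >= 0.9 & homog$mean_ratio <= 1.1
      out$notes <- c(out$notes, sprintf(
        "null calibration (%s): mean ratio %.3f [%s]",
        homog$condition, homog$mean_ratio, ifelse(ok, "pass", "FAIL")))
    }
  }
  if (!is.null(out$dispersion)) {
    agg <- tapply(out$dispersion$sd, out$dispersion$injection_age, mean)
    out$notes <- c(out$notes, sprintf("mean radial-position SD at E%s: %.3f",
                                      names(agg), agg))
  }
  if (length(out$notes) == 0) out$notes <- "empty run directory; nothing to report"
  writeLines(out$notes, file.path(run_dir, "report.txt"))
  out
}
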