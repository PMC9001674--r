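#' Specification of a simulated single-cell count data set
#'
#' Describes a genes-by-cells negative-binomial count matrix with latent
#' subtype programs per condition.  All conditions share one set of
#' baseline per-gene means; within a condition, each of `k_subtypes`
#' subtypes up-regulates its own disjoint block of `program_size` genes by
#' `2^effect_logfc`.  Dropout is independent Bernoulli zeroing, and the
#' first `ceiling(mito_gene_frac * n_genes)` genes are flagged
#' mitochondrial.
#'
#' @param n_genes Total number of genes.
#' @param mito_gene_frac Fraction of genes flagged mitochondrial.
#' @param conditions List of condition descriptions as produced by
#'   [sim_condition()].
#' @param seed Integer seed.
#' @return An object of class `expr_sim_spec`.
#' @export
expr_sim_spec <- function(n_genes = 1000,
                          mito_gene_frac = 0.02,
                          conditions = list(sim_condition()),
                          seed = 1L) {
  stopifnot(n_genes >= 1, mito_gene_frac >= 0, mito_gene_frac <= 1,
            length(conditions) >= 1)
  conditions <- lapply(conditions, function(cc) {
    stopifnot(inherits(cc, "sim_condition"))
    cc
  })
  labels <- vapply(conditions, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("condition labels must be unique", call. = FALSE)
  ## program genes are only materialized for conditions with latent structure
  total_program <- max(c(0, vapply(conditions, function(cc)
    if (cc$k_subtypes > 1) cc$k_subtypes * cc$program_size else 0,
    numeric(1))))
  if (total_program > n_genes)
    stop("subtype programs need more genes than n_genes provides", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 mito_gene_frac = mito_gene_frac,
                 conditions = conditions, seed = as.integer(seed)),
            class = "expr_sim_spec")
}

#' One simulated condition (birthdate x stage) of a count data set
#'
#' @param label Condition label, conventionally `"<birthdate>_<stage>"`
#'   (e.g. `"E13_N1d"`); used to populate the `birthdate` and `stage` cell
#'   metadata when it matches that pattern.
#' @param n_cells Cells in the condition.
#' @param k_subtypes Number of latent subtypes (1 = homogeneous).
#' @param subtype_props Mixing proportions, summing to 1.
#' @param program_size Genes per subtype program (disjoint across subtypes).
#' @param effect_logfc log2 fold change applied to a subtype's program genes
#'   in its own cells.
#' @param nb_mean_shape Shape of the gamma distribution baseline gene means
#'   are drawn from (scale fixed so the mean expression level is ~5 counts).
#' @param nb_dispersion Negative-binomial dispersion (`size = 1/dispersion`;
#'   variance = mu + dispersion * mu^2).
#' @param dropout_rate Probability that any count is independently zeroed.
#' @return An object of class `sim_condition`.
#' @export
sim_condition <- function(label = "E13_N1d",
                          n_cells = 300,
                          k_subtypes = 1,
                          subtype_props = rep(1 / k_subtypes, k_subtypes),
                          program_size = 40,
                          effect_logfc = 2,
                          nb_mean_shape = 0.5,
                          nb_dispersion = 0.5,
                          dropout_rate = 0.1) {
  stopifnot(n_cells >= 0, k_subtypes >= 1, program_size >= 0,
            nb_dispersion > 0, dropout_rate >= 0, dropout_rate <= 1)
  if (abs(sum(subtype_props) - 1) > 1e-9)
    stop("subtype_props must sum to 1", call. = FALSE)
  if (length(subtype_props) != k_subtypes)
    stop("subtype_props length must equal k_subtypes", call. = FALSE)
  structure(list(label = label, n_cells = as.integer(n_cells),
                 k_subtypes = as.integer(k_subtypes),
                 subtype_props = subtype_props,
                 program_size = as.integer(program_size),
                 effect_logfc = effect_logfc,
                 nb_mean_shape = nb_mean_shape,
                 nb_dispersion = nb_dispersion,
                 dropout_rate = dropout_rate),
            class = "sim_condition")
}

#' Simulate a count matrix with latent subtype structure
#'
#' Baseline per-gene means are drawn once and shared across all conditions;
#' cells of subtype `s` have their subtype's program genes multiplied by
#' `2^effect_logfc` before negative-binomial sampling; dropout then zeroes
#' each entry independently.  Ground-truth subtype labels are kept in the
#' cell metadata (`subtype_truth`).  Deterministic given the spec seed.
#'
#' Program gene blocks are taken from the tail of the gene list (the head
#' holds the mitochondrial flag block), identically across conditions:
#' subtype `s` of every condition uses block `s`.  When a condition has
#' `k_subtypes = 1` no program genes are perturbed at all, giving an
#' exchangeable homogeneous null.
#'
#' @param spec An [expr_sim_spec()].
#' @return A [count_matrix()] whose `cell_meta` carries `birthdate`,
#'   `stage`, `condition`, `subtype_truth` and a synthetic
#'   `radial_position`, and whose `gene_meta` carries program membership in
#'   an integer `program` column (`NA` for background genes); the same
#'   blocks are also attached as attribute `program_genes` on the fresh
#'   object.
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "expr_sim_spec"))
  with_seed(spec$seed, {
    G <- spec$n_genes
    n_mito <- ceiling(spec$mito_gene_frac * G)
    gene_ids <- sprintf("gene%05d", seq_len(G))
    if (n_mito > 0) gene_ids[seq_len(n_mito)] <- sprintf("mt-gene%03d", seq_len(n_mito))
    ## baseline means are shared across conditions; drawn with the first
    ## condition's shape parameter
    shp <- spec$conditions[[1]]$nb_mean_shape
    base_mu <- stats::rgamma(G, shape = shp, scale = 5 / shp)
    base_mu <- pmax(base_mu, 1e-3)

    structured <- Filter(function(cc) cc$k_subtypes > 1, spec$conditions)
    max_k <- max(c(1L, vapply(structured, `[[`, integer(1), "k_subtypes")))
    psize <- max(c(0L, vapply(structured, `[[`, integer(1), "program_size")))
    ## program blocks live at the tail of the gene list, clear of the mito block
    prog_blocks <- vector("list", max_k)
    if (psize > 0) {
      tail_start <- G - max_k * psize + 1
      if (tail_start <= n_mito)
        stop("not enough genes for disjoint subtype programs", call. = FALSE)
      for (s in seq_len(max_k)) {
        idx <- seq.int(tail_start + (s - 1) * psize, length.out = psize)
        prog_blocks[[s]] <- gene_ids[idx]
      }
    }

    mats <- list(); metas <- list()
    for (cc in spec$conditions) {
      n <- cc$n_cells
      if (n == 0L) next
      subtype <- sample.int(cc$k_subtypes, n, replace = TRUE, prob = cc$subtype_props)
      mu <- matrix(base_mu, nrow = G, ncol = n)
      if (cc$k_subtypes > 1 && cc$program_size > 0) {
        for (s in seq_len(cc$k_subtypes)) {
          gi <- match(prog_blocks[[s]][seq_len(cc$program_size)], gene_ids)
          ci <- which(subtype == s)
          if (length(ci)) mu[gi, ci] <- mu[gi, ci] * 2^cc$effect_logfc
        }
      }
      ## inverse-CDF sampling on a uniform draw per entry: specs differing
      ## only in effect size share all randomness (common random numbers),
      ## so effect-size ladders are monotonically coupled
      u <- matrix(stats::runif(G * n), nrow = G)
      cnt <- matrix(stats::qnbinom(u, mu = mu, size = 1 / cc$nb_dispersion),
                    nrow = G)
      u_drop <- matrix(stats::runif(G * n), nrow = G)
      if (cc$dropout_rate > 0) cnt <- cnt * (u_drop >= cc$dropout_rate)
      mats[[cc$label]] <- cnt
      parts <- strsplit(cc$label, "_", fixed = TRUE)[[1]]
      metas[[cc$label]] <- data.frame(
        cell_id = sprintf("%s_c%04d", cc$label, seq_len(n)),
        birthdate = parts[1],
        stage = if (length(parts) > 1) paste(parts[-1], collapse = "_") else NA_character_,
        condition = cc$label,
        subtype_truth = subtype,
        ## synthetic recorded depth: subtypes stacked along the radial axis
        radial_position = pmin(1, pmax(0, stats::rnorm(
          n, mean = subtype / (cc$k_subtypes + 1), sd = 0.08))),
        stringsAsFactors = FALSE
      )
    }
    counts <- do.call(cbind, mats)
    cell_meta <- do.call(rbind, metas)
    rownames(cell_meta) <- NULL
    dimnames(counts) <- list(gene_ids, cell_meta$cell_id)
    program <- rep(NA_integer_, G)
    for (s in seq_along(prog_blocks)) {
      if (!is.null(prog_blocks[[s]]))
        program[match(prog_blocks[[s]], gene_ids)] <- s
    }
    gm <- data.frame(gene_id = gene_ids,
                     mito = seq_len(G) <= n_mito,
                     program = program,
                     stringsAsFactors = FALSE)
    out <- count_matrix(counts, gene_meta = gm, cell_meta = cell_meta)
    attr(out, "program_genes") <- prog_blocks
    out
  })
}
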