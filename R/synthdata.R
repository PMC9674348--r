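#' Configuration for the synthetic-data generators
#'
#' Describes a synthetic secretome experiment (cell types x replicates with
#' MNAR missingness and planted cell-type-specific secretion effects) and a
#' synthetic tissue expression atlas (with planted adipose-enriched genes).
#' Each generator draws from its own RNG stream seeded by a fixed offset from
#' `seed`, so generating one artifact never shifts another.
#'
#' Defaults describe a realistic label-free MS world: log2 LFQ intensities
#' centred near 25 with between-protein SD 2, replicate SD 0.5, and a
#' logistic missingness curve that preferentially censors low-abundance
#' values (~50% missing around log2 intensity 22). The atlas mimics a log2
#' microarray compendium (88 tissues, within-tissue SD 0.3) with adipose
#' enrichment planted at +6 log2 in the two adipose tissues.
#'
#' @param n_proteins number of proteins in the conditioned-medium matrix.
#' @param n_cell_types,n_replicates design of the CM experiment.
#' @param frac_differential fraction of proteins carrying a planted
#'   cell-type-specific secretion effect.
#' @param effect_log2 magnitude (log2 units) of the planted effects.
#' @param base_mu,base_sigma location/scale of per-protein baseline log2
#'   intensity.
#' @param rep_sigma within-cell-type replicate SD (log2 units).
#' @param missing_beta0,missing_beta1 intercept/slope of the logistic
#'   missingness model: `P(missing) = plogis(missing_beta0 - missing_beta1 *
#'   log2intensity)`. A positive slope makes low intensities preferentially
#'   missing (MNAR). `missing_beta1 = 0` with a very negative `missing_beta0`
#'   disables missingness.
#' @param n_tissues number of atlas tissues (two of which are adipose).
#' @param n_atlas_replicates replicates per tissue in the atlas.
#' @param n_adipose_genes number of planted adipose-enriched genes.
#' @param atlas_effect_log2 planted adipose enrichment (log2 units).
#' @param atlas_mu,atlas_sigma,atlas_rep_sigma baseline location, per-gene
#'   scale and within-tissue replicate SD of atlas log2 expression.
#' @param seed master RNG seed; fixed seed implies byte-identical outputs.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 600,
                         n_cell_types = 3,
                         n_replicates = 3,
                         frac_differential = 0.5,
                         effect_log2 = 4,
                         base_mu = 25,
                         base_sigma = 2,
                         rep_sigma = 0.5,
                         missing_beta0 = 17.6,
                         missing_beta1 = 0.8,
                         n_tissues = 88,
                         n_atlas_replicates = 3,
                         n_adipose_genes = 5,
                         atlas_effect_log2 = 6,
                         atlas_mu = 7,
                         atlas_sigma = 1,
                         atlas_rep_sigma = 0.3,
                         seed = 1L) {
  cfg <- list(
    n_proteins = as.integer(n_proteins), n_cell_types = as.integer(n_cell_types),
    n_replicates = as.integer(n_replicates), frac_differential = frac_differential,
    effect_log2 = effect_log2, base_mu = base_mu, base_sigma = base_sigma,
    rep_sigma = rep_sigma,
    missing_beta0 = missing_beta0, missing_beta1 = missing_beta1,
    n_tissues = as.integer(n_tissues),
    n_atlas_replicates = as.integer(n_atlas_replicates),
    n_adipose_genes = as.integer(n_adipose_genes),
    atlas_effect_log2 = atlas_effect_log2,
    atlas_mu = atlas_mu, atlas_sigma = atlas_sigma,
    atlas_rep_sigma = atlas_rep_sigma, seed = as.integer(seed)
  )
  num <- unlist(cfg[setdiff(names(cfg), "seed")])
  if (any(!is.finite(num))) stop("non-finite config parameter", call. = FALSE)
  counts <- c("n_proteins", "n_cell_types", "n_replicates", "n_tissues",
              "n_atlas_replicates")
  if (any(unlist(cfg[counts]) < 1)) stop("counts must be >= 1", call. = FALSE)
  if (cfg$frac_differential < 0 || cfg$frac_differential > 1)
    stop("frac_differential must lie in [0,1]", call. = FALSE)
  if (cfg$n_adipose_genes < 0) stop("n_adipose_genes must be >= 0", call. = FALSE)
  structure(cfg, class = "synth_config")
}

# fixed per-artifact stream offsets (kept < 2^31 via modular arithmetic)
substream <- function(seed, offset) as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)

#' Simulate a conditioned-medium intensity matrix with known ground truth
#'
#' Per protein, a baseline log2 intensity is drawn from
#' `Normal(base_mu, base_sigma)`; a fraction `frac_differential` of proteins
#' additionally carry a `+effect_log2` shift in one randomly chosen cell
#' type. Replicate values scatter around their cell-type mean with SD
#' `rep_sigma`. Each replicate value is then censored (set to 0, i.e.
#' missing) independently with probability
#' `plogis(missing_beta0 - missing_beta1 * log2intensity)`, reproducing the
#' missing-not-at-random structure of label-free MS where low-abundance
#' values drop out preferentially. The iBAQ layer is the LFQ layer scaled by
#' a per-protein lognormal factor (iBAQ is only used for abundance ranking,
#' never inference).
#'
#' @param config a [synth_config()].
#' @return a list with elements `matrix` (an [intensity_matrix()]; cell types
#'   `CT1..CTk`, samples `CT<i>_<r>`) and `truth` (a tibble `protein_id`,
#'   `gene`, `differential`, `shifted_type`, plus one `mean_<type>` column of
#'   true cell-type means per cell type).
#' @export
simulate_cm_matrix <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(substream(config$seed, 101), {
    p <- config$n_proteins
    k <- config$n_cell_types
    r <- config$n_replicates
    types <- paste0("CT", seq_len(k))
    ids <- sprintf("P%04d", seq_len(p))
    genes <- sprintf("Gene%04d", seq_len(p))

    base <- stats::rnorm(p, config$base_mu, config$base_sigma)
    n_diff <- round(config$frac_differential * p)
    diff_idx <- if (n_diff > 0) sort(sample.int(p, n_diff)) else integer(0)
    shifted_type <- rep(NA_character_, p)
    shifted_type[diff_idx] <- sample(types, n_diff, replace = TRUE)

    means <- matrix(base, nrow = p, ncol = k, dimnames = list(ids, types))
    for (j in seq_len(k))
      means[, j] <- means[, j] +
        ifelse(!is.na(shifted_type) & shifted_type == types[j],
               config$effect_log2, 0)

    samples <- tibble::tibble(
      sample = paste0(rep(types, each = r), "_", rep(seq_len(r), k)),
      group = rep(types, each = r),
      replicate = rep(seq_len(r), k)
    )
    log2lfq <- means[, samples$group, drop = FALSE] +
      matrix(stats::rnorm(p * nrow(samples), 0, config$rep_sigma), nrow = p)
    colnames(log2lfq) <- samples$sample

    p_miss <- stats::plogis(config$missing_beta0 - config$missing_beta1 * log2lfq)
    miss <- matrix(stats::runif(length(p_miss)) < p_miss, nrow = p)
    lfq <- 2^log2lfq
    lfq[miss] <- 0

    ibaq_scale <- stats::rlnorm(p, 0, 1)
    ibaq <- lfq * ibaq_scale

    truth <- tibble::tibble(
      protein_id = ids, gene = genes,
      differential = seq_len(p) %in% diff_idx,
      shifted_type = shifted_type
    )
    for (j in seq_len(k)) truth[[paste0("mean_", types[j])]] <- means[, j]

    list(
      matrix = intensity_matrix(lfq, ibaq, samples, gene_symbols = genes),
      truth = truth
    )
  })
}

#' Simulate a tissue expression atlas with planted adipose-enriched genes
#'
#' Genes x tissues x replicates log2 expression. The first two tissues are
#' the designated adipose depots (`eWAT`, `BAT`); `n_adipose_genes` genes are
#' elevated there by `atlas_effect_log2` while all other genes are
#' exchangeable across tissues. Gene symbols match the conditioned-medium
#' simulation (`Gene0001`, ...) so the two artifacts can be joined, and the
#' planted genes are the first `n_adipose_genes` symbols.
#'
#' @param config a [synth_config()]; requires `n_tissues >= 3`.
#' @param n_genes number of atlas genes (default `n_proteins`).
#' @return a list with `atlas` (a `tissue_atlas`: log2 expression matrix
#'   genes x (tissue, replicate) columns, tissue metadata, adipose labels)
#'   and `truth` (tibble `gene`, `adipose_enriched`).
#' @export
simulate_atlas <- function(config, n_genes = config$n_proteins) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_tissues < 3)
    stop("atlas needs n_tissues >= 3 (two adipose + at least one other)",
         call. = FALSE)
  withr::with_seed(substream(config$seed, 202), {
    tns <- c("eWAT", "BAT",
             sprintf("Tissue%02d", seq_len(config$n_tissues - 2)))
    r <- config$n_atlas_replicates
    genes <- sprintf("Gene%04d", seq_len(n_genes))
    n_pl <- if (config$atlas_effect_log2 == 0) 0L else
      min(config$n_adipose_genes, n_genes)
    planted <- genes[seq_len(n_pl)]

    base <- stats::rnorm(n_genes, config$atlas_mu, config$atlas_sigma)
    cols <- tibble::tibble(
      tissue = rep(tns, each = r),
      replicate = rep(seq_len(r), length(tns))
    )
    cols$label <- paste0(cols$tissue, "_", cols$replicate)
    expr <- matrix(base, nrow = n_genes, ncol = nrow(cols),
                   dimnames = list(genes, cols$label))
    adipose_cols <- cols$tissue %in% c("eWAT", "BAT")
    expr[seq_len(n_pl), adipose_cols] <-
      expr[seq_len(n_pl), adipose_cols] + config$atlas_effect_log2
    expr <- expr + matrix(stats::rnorm(length(expr), 0, config$atlas_rep_sigma),
                          nrow = n_genes)
    atlas <- tissue_atlas(expr, cols[c("label", "tissue", "replicate")],
                          adipose_tissues = c("eWAT", "BAT"))
    list(
      atlas = atlas,
      truth = tibble::tibble(gene = genes, adipose_enriched = genes %in% planted)
    )
  })
}

#' Simulate a secretion-predictor annotation table
#'
#' Emulates the score table a practitioner assembles from signal-peptide,
#' transmembrane, non-classical-secretion, GPI and subcellular-localization
#' predictors. Proteins named in `secreted` receive classical-secretion-like
#' scores (signal score > 0.5, 0–1 TM segments, extracellular localization
#' and an extracellular GO component term); the rest receive intracellular
#' profiles.
#'
#' @param protein_ids character vector of protein ids.
#' @param secreted character vector (subset of `protein_ids`) to be given
#'   secreted-like annotations.
#' @param seed RNG seed.
#' @return a tibble in the layout [classify_secretion()] accepts, with a
#'   `cc_terms` column of semicolon-joined GO component ids.
#' @export
simulate_secretion_annotation <- function(protein_ids, secreted = character(),
                                          seed = 1L) {
  withr::with_seed(substream(seed, 303), {
    n <- length(protein_ids)
    is_sec <- protein_ids %in% secreted
    tibble::tibble(
      protein_id = protein_ids,
      signal_peptide_score = ifelse(is_sec, stats::runif(n, 0.7, 1),
                                    stats::runif(n, 0, 0.4)),
      tm_count = ifelse(is_sec, sample(0:1, n, replace = TRUE),
                        sample(0:6, n, replace = TRUE)),
      nonclassical_score = stats::runif(n, 0, 0.5),
      gpi_specificity = stats::runif(n, 0, 90),
      localization_label = ifelse(is_sec, "Extracellular",
                                  sample(c("Cytoplasm", "Nucleus", "Mitochondrion"),
                                         n, replace = TRUE)),
      cc_terms = ifelse(is_sec, "5576;5615", "5829")
    )
  })
}
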