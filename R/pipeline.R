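#' Configuration for a full synthetic pipeline run
#'
#' Gathers every stage parameter — the synthetic world, detection filter,
#' imputation, permutation ANOVA, clustering, secretion annotation, atlas
#' scoring and the candidate threshold — under one master seed. Every
#' stochastic stage draws from its own substream derived from `seed` by a
#' fixed offset, so an identical config yields identical outputs.
#'
#' @param synth a [synth_config()]; its `seed` is overridden by `seed`.
#' @param min_detected,per_group_size detection-filter rule.
#' @param impute_width,impute_downshift left-shifted Gaussian parameters.
#' @param n_perm,q_threshold permutation-ANOVA parameters.
#' @param k number of profile clusters.
#' @param frac_secreted fraction of proteins given secreted-like predictor
#'   annotations in the synthetic annotation table.
#' @param atlas_mode adipose reference mode for [enrichment_score()].
#' @param candidate_threshold enrichment-score cut-off (percent, strict >).
#' @param n_serum size of the synthetic nascent-serum gene set (always
#'   includes the planted adipose-enriched genes).
#' @param seed master seed.
#' @return a `run_config` list.
#' @export
run_config <- function(synth = synth_config(),
                       min_detected = 2, per_group_size = synth$n_replicates,
                       impute_width = 0.3, impute_downshift = 1.8,
                       n_perm = 250, q_threshold = 0.01,
                       k = 4,
                       frac_secreted = 0.7,
                       atlas_mode = "combined",
                       candidate_threshold = 80,
                       n_serum = 100,
                       seed = 1L) {
  synth$seed <- as.integer(seed)
  cfg <- list(synth = synth,
              min_detected = as.integer(min_detected),
              per_group_size = as.integer(per_group_size),
              impute_width = impute_width, impute_downshift = impute_downshift,
              n_perm = as.integer(n_perm), q_threshold = q_threshold,
              k = as.integer(k),
              frac_secreted = frac_secreted, atlas_mode = atlas_mode,
              candidate_threshold = as.numeric(candidate_threshold),
              n_serum = as.integer(n_serum), seed = as.integer(seed))
  structure(cfg, class = "run_config")
}

#' Serialize / restore a run configuration (JSON)
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @return `path` invisibly / the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(lapply(config, function(x)
    if (inherits(x, "synth_config")) unclass(x) else x)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  synth <- do.call(synth_config, raw$synth)
  do.call(run_config, c(list(synth = synth),
                        raw[setdiff(names(raw), c("synth", "per_group_size"))]))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full synthetic discovery pipeline
#'
#' Executes simulate -> parse -> QC-exclude -> detection-filter -> log2 ->
#' impute -> permutation ANOVA -> cluster -> abundance ranking -> secretion
#' classification -> atlas enrichment scoring -> candidate intersection, and
#' assembles a manifest of per-stage row counts, parameters and seeds.
#' Identical configs produce identical manifests and outputs.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, stage outputs are written
#'   as plain-text files (protein-groups TSV, tidy CSVs, manifest JSON).
#' @return a list: `cm` (simulation + truth), `filtered`, `imputed`,
#'   `anova`, `clusters`, `abundance`, `secretion`, `atlas`, `scores`,
#'   `report`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  cs <- config$synth

  sim <- run_stage("simulate", simulate_cm_matrix(cs))
  m <- sim$matrix
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    pg_path <- file.path(out_dir, "protein_groups.tsv")
    write_protein_groups(m, pg_path)
    m <- run_stage("parse", read_protein_groups(pg_path, sample_map = m$samples))
  }
  retained <- run_stage("exclude", exclude_flagged(m))
  filtered <- run_stage("filter", filter_detected(
    retained, detection_filter_spec(config$min_detected, config$per_group_size)))
  logm <- run_stage("log2", log2_transform(filtered))
  imputed <- run_stage("impute", impute_left_gaussian(
    logm, impute_spec(config$impute_width, config$impute_downshift,
                      seed = substream(config$seed, 404))))
  groups <- filtered$samples$group
  anova <- run_stage("anova", permutation_fdr_anova(
    imputed, groups, n_perm = config$n_perm,
    q_threshold = config$q_threshold, seed = substream(config$seed, 505)))

  sig_ids <- anova$protein_id[anova$significant]
  clusters <- NULL
  if (length(sig_ids) >= config$k) {
    z <- run_stage("cluster", zscore_rows(imputed[sig_ids, , drop = FALSE]))
    clusters <- run_stage("cluster", hierarchical_cluster(
      z, k = config$k, groups = groups))
  }
  abundance <- run_stage("rank", rank_by_abundance(filtered, clusters))

  secreted_n <- round(config$frac_secreted * nrow(filtered$lfq))
  secreted_ids <- withr::with_seed(substream(config$seed, 606),
                                   sample(rownames(filtered$lfq), secreted_n))
  ann <- run_stage("secretion", simulate_secretion_annotation(
    rownames(filtered$lfq), secreted = secreted_ids,
    seed = substream(config$seed, 606)))
  verdicts <- run_stage("secretion", classify_secretion(ann))
  component <- run_stage("secretion", tally_cell_component(ann))

  atl <- run_stage("atlas", simulate_atlas(cs))
  scores <- run_stage("score", enrichment_score(atl$atlas, mode = config$atlas_mode))

  cm_genes <- filtered$gene_symbols
  planted <- atl$truth$gene[atl$truth$adipose_enriched]
  other_genes <- setdiff(atl$truth$gene, planted)
  serum_genes <- withr::with_seed(substream(config$seed, 707), {
    extra <- min(max(config$n_serum - length(planted), 0), length(other_genes))
    c(planted, sample(other_genes, extra))
  })
  report <- run_stage("candidates", build_candidates(
    cm_genes, scores, serum_genes, threshold = config$candidate_threshold))

  manifest <- list(
    package = "secretomics",
    seed = config$seed,
    params = list(
      n_perm = config$n_perm, q_threshold = config$q_threshold,
      min_detected = config$min_detected, k = config$k,
      impute = c(width = config$impute_width, downshift = config$impute_downshift),
      atlas_mode = config$atlas_mode,
      candidate_threshold = config$candidate_threshold,
      fdr_estimator = attr(anova, "estimator")
    ),
    counts = list(
      parsed = nrow(m$lfq),
      excluded = nrow(m$lfq) - nrow(retained$lfq),
      retained = nrow(retained$lfq),
      filtered = nrow(filtered$lfq),
      significant = length(sig_ids),
      clusters = if (is.null(clusters)) integer(0) else
        as.vector(table(clusters$cluster)),
      secretion_any = sum(verdicts$any_criterion),
      atlas_genes = nrow(atl$atlas$expr),
      score_pass = sum(scores$score_percent > config$candidate_threshold),
      serum = length(serum_genes),
      candidates = sum(report$candidate)
    )
  )

  if (!is.null(out_dir)) {
    readr::write_csv(sim$truth, file.path(out_dir, "cm_truth.csv"), progress = FALSE)
    readr::write_csv(tibble::as_tibble(anova), file.path(out_dir, "anova.csv"), progress = FALSE)
    if (!is.null(clusters))
      readr::write_csv(tibble::as_tibble(clusters), file.path(out_dir, "clusters.csv"), progress = FALSE)
    readr::write_csv(abundance, file.path(out_dir, "abundance.csv"), progress = FALSE)
    readr::write_csv(verdicts, file.path(out_dir, "secretion_verdicts.csv"), progress = FALSE)
    readr::write_csv(tibble::as_tibble(scores), file.path(out_dir, "enrichment_scores.csv"), progress = FALSE)
    readr::write_csv(tibble::as_tibble(report), file.path(out_dir, "candidate_report.csv"), progress = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(cm = sim, filtered = filtered, imputed = imputed, anova = anova,
       clusters = clusters, abundance = abundance,
       secretion = list(annotation = ann, verdicts = verdicts,
                        component = component),
       atlas = atl, scores = scores, report = report, manifest = manifest)
}
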