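#' Z-score transform each protein row
#'
#' Centres and scales every row to mean 0, SD 1 (population SD, i.e.
#' dividing by `sqrt(mean((x - mean(x))^2))`) — the transform applied before
#' clustering so the heatmap shows relative secretion profiles, not absolute
#' abundance.
#'
#' @param x numeric matrix with >= 2 columns.
#' @return the row-standardized matrix.
#' @export
zscore_rows <- function(x) {
  if (ncol(x) < 2) stop("need >= 2 samples", call. = FALSE)
  sds <- sqrt(rowMeans((x - rowMeans(x))^2))
  if (any(sds == 0)) {
    bad <- rownames(x)[sds == 0] %||% which(sds == 0)
    stop("zero-variance row(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  (x - rowMeans(x)) / sds
}

#' Complete-linkage hierarchical clustering of secretion profiles
#'
#' Agglomerative clustering with complete linkage on the Euclidean distance
#' between z-scored rows, cut to exactly `k` clusters. Cluster labels are
#' renumbered by descending mean z-score in `ref_group` (the first sample
#' group by default), a deterministic convention mimicking the usual
#' cluster-1..k heatmap ordering.
#'
#' @param z z-scored matrix (proteins x samples), e.g. from [zscore_rows()].
#' @param k number of clusters (default 4).
#' @param groups optional label per column, used for the relabelling
#'   convention.
#' @param ref_group group whose mean z-score orders the cluster labels.
#' @return a `cluster_assignment`: tibble `protein_id`, `cluster`, with the
#'   `hclust` merge history in attribute `"dendrogram"` and the metric /
#'   linkage recorded in attributes.
#' @export
hierarchical_cluster <- function(z, k = 4, groups = NULL, ref_group = NULL) {
  if (k > nrow(z)) stop("k exceeds number of proteins", call. = FALSE)
  hc <- stats::hclust(stats::dist(z, method = "euclidean"),
                      method = "complete")
  raw <- stats::cutree(hc, k = k)
  if (is.null(groups)) groups <- colnames(z)
  if (is.null(ref_group)) ref_group <- groups[1]
  if (!is.null(ref_group) && any(groups == ref_group)) {
    ref_mean <- rowMeans(z[, groups == ref_group, drop = FALSE])
    by_cluster <- tapply(ref_mean, raw, mean)
    relabel <- match(names(sort(by_cluster, decreasing = TRUE)),
                     names(by_cluster))
    labels <- match(raw, relabel)
  } else {
    labels <- unname(raw)  # no reference group: keep cutree labels
  }
  out <- tibble::tibble(
    protein_id = rownames(z) %||% as.character(seq_len(nrow(z))),
    cluster = labels
  )
  structure(out, class = c("cluster_assignment", class(out)),
            k = k, linkage = "complete", distance = "euclidean",
            dendrogram = hc)
}

#' Rank proteins by iBAQ abundance within their clusters
#'
#' Sorts proteins by decreasing mean iBAQ intensity (molar-abundance proxy),
#' carrying cluster labels along; ties keep input order (stable sort).
#'
#' @param m an [intensity_matrix()] providing the iBAQ layer.
#' @param assignment a [hierarchical_cluster()] result (or any tibble with
#'   `protein_id`, `cluster`); proteins absent from it get cluster `NA`.
#' @return a tibble `protein_id`, `gene`, `cluster`, `mean_ibaq`, `rank`.
#' @export
rank_by_abundance <- function(m, assignment = NULL) {
  out <- tibble::tibble(
    protein_id = rownames(m$ibaq),
    gene = m$gene_symbols,
    mean_ibaq = rowMeans(m$ibaq)
  )
  if (!is.null(assignment))
    out <- dplyr::left_join(out,
                            tibble::as_tibble(assignment)[c("protein_id", "cluster")],
                            by = "protein_id")
  else out$cluster <- NA_integer_
  out <- out[order(-out$mean_ibaq), ]  # order() is stable: ties keep input order
  out$rank <- seq_len(nrow(out))
  out[c("protein_id", "gene", "cluster", "mean_ibaq", "rank")]
}

#' Hypergeometric overrepresentation of annotation terms in a cluster
#'
#' For each term, the one-sided hypergeometric tail probability of drawing
#' at least the observed overlap when `|cluster|` genes are sampled from the
#' background, BH-adjusted across terms. This is an explicit, offline
#' stand-in for web-service annotation enrichment; term lists are inputs.
#'
#' @param cluster_genes character vector; must be a subset of
#'   `background_genes`.
#' @param background_genes character vector (the detected-protein universe).
#' @param term_map tibble/data.frame with columns `term`, `gene`.
#' @param top_n optionally keep only the `top_n` most significant terms.
#' @return a tibble `term`, `overlap`, `term_size`, `cluster_size`,
#'   `background_size`, `p`, `p_adj`, sorted by `p`.
#' @export
overrepresentation <- function(cluster_genes, background_genes, term_map,
                               top_n = NULL) {
  missing_genes <- setdiff(cluster_genes, background_genes)
  if (length(missing_genes) > 0)
    stop("cluster gene(s) absent from background: ",
         paste(utils::head(missing_genes, 5), collapse = ", "), call. = FALSE)
  term_map <- tibble::as_tibble(term_map)
  term_map <- term_map[term_map$gene %in% background_genes, ]
  N <- length(unique(background_genes))
  n_draw <- length(unique(cluster_genes))
  res <- term_map |>
    dplyr::group_by(term = .data$term) |>
    dplyr::summarise(
      overlap = length(intersect(unique(.data$gene), cluster_genes)),
      term_size = length(unique(.data$gene)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      cluster_size = n_draw,
      background_size = N,
      p = stats::phyper(.data$overlap - 1, .data$term_size,
                        N - .data$term_size, n_draw, lower.tail = FALSE),
      p_adj = stats::p.adjust(.data$p, method = "BH")
    ) |>
    dplyr::arrange(.data$p)
  if (!is.null(top_n)) res <- utils::head(res, top_n)
  res
}
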