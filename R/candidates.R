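#' Nominate candidate adipokines by three-criterion intersection
#'
#' A gene is a candidate when it is (1) detected in adipocyte conditioned
#' medium, (2) adipose-enriched with a tissue enrichment score strictly
#' above `threshold` percent, and (3) present in the nascent serum proteome.
#' Gene symbols are case-normalized before joining; the report covers the
#' union of the three evidence layers in alphabetical order.
#'
#' @param cm_detected character vector of gene symbols detected in
#'   conditioned medium.
#' @param scores an [enrichment_score()] tibble (needs `gene`,
#'   `score_percent`); genes absent from it score `NA` and cannot pass.
#' @param serum_detected character vector of gene symbols detected in serum.
#' @param threshold enrichment-score cut-off in percent (strict `>`,
#'   default 80).
#' @return a `candidate_report` tibble: `gene`, `in_cm`,
#'   `enrichment_score`, `score_pass`, `in_serum`, `candidate`.
#' @export
build_candidates <- function(cm_detected, scores, serum_detected,
                             threshold = 80) {
  norm <- function(v) toupper(trimws(v))
  check_dupes <- function(v, what) {
    d <- unique(v[duplicated(v)])
    if (length(d) > 0)
      stop("duplicate ", what, " after normalization: ",
           paste(utils::head(d, 5), collapse = ", "), call. = FALSE)
    v
  }
  cm <- check_dupes(norm(cm_detected), "CM symbols")
  serum <- check_dupes(norm(serum_detected), "serum symbols")
  scores <- tibble::as_tibble(scores)
  score_tbl <- tibble::tibble(gene = check_dupes(norm(scores$gene), "score symbols"),
                              enrichment_score = scores$score_percent)
  all_genes <- sort(unique(c(cm, serum, score_tbl$gene)))
  out <- tibble::tibble(gene = all_genes) |>
    dplyr::left_join(score_tbl, by = "gene") |>
    dplyr::mutate(
      in_cm = .data$gene %in% cm,
      score_pass = !is.na(.data$enrichment_score) &
        .data$enrichment_score > threshold,
      in_serum = .data$gene %in% serum,
      candidate = .data$in_cm & .data$score_pass & .data$in_serum
    ) |>
    dplyr::select("gene", "in_cm", "enrichment_score", "score_pass",
                  "in_serum", "candidate")
  structure(out, class = c("candidate_report", class(out)),
            threshold = threshold)
}

#' Summarise a candidate report (the discovery funnel counts)
#' @param x a `candidate_report`.
#' @param ... unused.
#' @return a one-row tibble of funnel counts.
#' @method glance candidate_report
#' @export
glance.candidate_report <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_cm = sum(x$in_cm),
    n_score_pass = sum(x$score_pass),
    n_serum = sum(x$in_serum),
    n_cm_and_enriched = sum(x$in_cm & x$score_pass),
    n_candidates = sum(x$candidate),
    threshold = attr(x, "threshold")
  )
}
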