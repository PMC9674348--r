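#' Rule-based secretion-route classification
#'
#' Applies the published predictor thresholds to a per-protein score table:
#'
#' * classical ER/Golgi secretion: signal-peptide score > 0.5 AND 0 or 1
#'   predicted transmembrane segments;
#' * non-classical secretion: non-classical score > 0.6 AND signal-peptide
#'   score <= 0.5 (so classical and non-classical are mutually exclusive by
#'   construction);
#' * GPI anchoring: GPI specificity > 99 (percent);
#' * predicted extracellular localization: case-insensitive label match on
#'   `"extracellular"`.
#'
#' All inequalities are strict where stated. A missing predictor output
#' (`NA`) contributes `FALSE` rather than an error, because real predictor
#' tables have dropouts; `any_criterion` is the OR of the four verdicts.
#'
#' @param annotations tibble with columns `protein_id`,
#'   `signal_peptide_score` (0–1), `tm_count` (integer >= 0),
#'   `nonclassical_score` (0–1), `gpi_specificity` (0–100),
#'   `localization_label`.
#' @return a tibble `protein_id`, `classical`, `nonclassical`, `gpi`,
#'   `extracellular_predicted`, `any_criterion`.
#' @export
classify_secretion <- function(annotations) {
  a <- tibble::as_tibble(annotations)
  need <- c("protein_id", "signal_peptide_score", "tm_count",
            "nonclassical_score", "gpi_specificity", "localization_label")
  missing_cols <- setdiff(need, names(a))
  if (length(missing_cols) > 0)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  rng_ok <- function(v, lo, hi) all(is.na(v) | (v >= lo & v <= hi))
  if (!rng_ok(a$signal_peptide_score, 0, 1)) stop("signal_peptide_score out of [0,1]", call. = FALSE)
  if (!rng_ok(a$nonclassical_score, 0, 1)) stop("nonclassical_score out of [0,1]", call. = FALSE)
  if (!rng_ok(a$gpi_specificity, 0, 100)) stop("gpi_specificity out of [0,100]", call. = FALSE)
  if (!all(is.na(a$tm_count) | (a$tm_count >= 0 & a$tm_count == round(a$tm_count))))
    stop("tm_count must be a non-negative integer", call. = FALSE)

  na_false <- function(v) !is.na(v) & v
  sig_high <- na_false(a$signal_peptide_score > 0.5)
  # absent signal-peptide output cannot certify the <= 0.5 condition either
  sig_low <- !is.na(a$signal_peptide_score) & a$signal_peptide_score <= 0.5
  tibble::tibble(
    protein_id = a$protein_id,
    classical = sig_high & na_false(a$tm_count <= 1),
    nonclassical = na_false(a$nonclassical_score > 0.6) & sig_low,
    gpi = na_false(a$gpi_specificity > 99),
    extracellular_predicted =
      na_false(tolower(trimws(a$localization_label)) == "extracellular"),
  ) |>
    dplyr::mutate(any_criterion = .data$classical | .data$nonclassical |
                    .data$gpi | .data$extracellular_predicted)
}

#' Completeness report for a predictor score table
#'
#' @param annotations as in [classify_secretion()].
#' @return a tibble `field`, `n_missing`, `frac_missing`.
#' @export
annotation_completeness <- function(annotations) {
  fields <- c("signal_peptide_score", "tm_count", "nonclassical_score",
              "gpi_specificity", "localization_label")
  tibble::tibble(
    field = fields,
    n_missing = vapply(fields, function(f) sum(is.na(annotations[[f]])), 0L),
    frac_missing = .data$n_missing / nrow(annotations)
  )
}

#' Default GO cellular-component display categories
#'
#' Maps the tracked numeric GO component term ids to the display categories
#' of the secretome annotation summary: Extracellular is the union of
#' extracellular region (5576), extracellular space (5615) and extracellular
#' matrix (31012); the remaining organelles map one-to-one.
#'
#' @return a tibble `term`, `category`.
#' @export
default_component_map <- function() {
  tibble::tribble(
    ~term, ~category,
    "5576", "Extracellular",   # extracellular region
    "5615", "Extracellular",   # extracellular space
    "31012", "Extracellular",  # extracellular matrix
    "5886", "PM",              # plasma membrane
    "5739", "Mito",            # mitochondrion
    "5783", "ER",              # endoplasmic reticulum
    "5794", "Golgi",           # Golgi apparatus
    "5829", "Cytosol",
    "5634", "Nucleus"
  )
}

#' Tally proteins per cellular-component category
#'
#' Counts, per display category, the proteins carrying at least one GO
#' component term mapped to that category; one protein may count in several
#' categories. Unknown term ids raise a warning and are skipped.
#'
#' @param annotations tibble with `protein_id` and `cc_terms`
#'   (semicolon-joined term ids, or a list-column of character vectors).
#' @param category_map tibble `term`, `category`
#'   (default [default_component_map()]).
#' @return a tibble `category`, `n`, `fraction` (of all proteins), ordered
#'   by decreasing count.
#' @export
tally_cell_component <- function(annotations, category_map = default_component_map()) {
  a <- tibble::as_tibble(annotations)
  terms <- a$cc_terms
  if (!is.list(terms))
    terms <- strsplit(ifelse(is.na(terms), "", terms), ";", fixed = TRUE)
  terms <- lapply(terms, function(v) trimws(v[nzchar(trimws(v))]))
  unknown <- setdiff(unique(unlist(terms)), category_map$term)
  if (length(unknown) > 0)
    warning("skipping unknown term id(s): ",
            paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  n_total <- nrow(a)
  cats <- unique(category_map$category)
  counts <- unname(vapply(cats, function(cat) {
    ids <- category_map$term[category_map$category == cat]
    sum(vapply(terms, function(v) any(v %in% ids), logical(1)))
  }, 0L))
  tibble::tibble(category = cats, n = counts,
                 fraction = counts / n_total) |>
    dplyr::arrange(dplyr::desc(.data$n))
}
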