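#' Detection-filter specification
#'
#' A protein is retained when it has at least `min_detected` quantified
#' replicates in at least one cell-type group — the "detected in at least
#' 2/3 replicates" rule.
#'
#' @param min_detected minimum quantified replicates within a group.
#' @param per_group_size expected replicates per group.
#' @return a `detection_filter_spec` list.
#' @export
detection_filter_spec <- function(min_detected = 2, per_group_size = 3) {
  if (!(min_detected > 0 && min_detected <= per_group_size))
    stop("need 0 < min_detected <= per_group_size", call. = FALSE)
  structure(list(min_detected = min_detected, per_group_size = per_group_size),
            class = "detection_filter_spec")
}

#' Filter proteins by within-group detection
#'
#' @param m an [intensity_matrix()]; groups are taken from `m$samples$group`.
#' @param spec a [detection_filter_spec()].
#' @return the filtered [intensity_matrix()], input order preserved.
#' @export
filter_detected <- function(m, spec = detection_filter_spec()) {
  groups <- m$samples$group
  sizes <- table(groups)
  if (any(sizes < spec$min_detected))
    stop("group size below min_detected: ",
         paste(names(sizes)[sizes < spec$min_detected], collapse = ", "),
         call. = FALSE)
  detected <- m$lfq > 0
  per_group <- t(rowsum(t(detected * 1), groups))  # proteins x groups counts
  keep <- apply(per_group >= spec$min_detected, 1, any)
  subset_proteins(m, keep)
}

#' Log2-transform LFQ intensities
#'
#' Positive intensities become log2 values; zeros (not quantified) become
#' `NA`. No imputation happens here.
#'
#' @param m an [intensity_matrix()].
#' @param layer `"lfq"` (default) or `"ibaq"`.
#' @return a numeric matrix (proteins x samples) with `NA` marking missing.
#' @export
log2_transform <- function(m, layer = c("lfq", "ibaq")) {
  layer <- match.arg(layer)
  x <- m[[layer]]
  if (any(x < 0, na.rm = TRUE)) stop("negative intensity", call. = FALSE)
  out <- log2(x)
  out[x == 0] <- NA_real_
  out
}

#' Imputation specification (left-shifted Gaussian)
#'
#' Perseus-convention imputation for missing-not-at-random label-free MS
#' data: missing values in each sample column are drawn from a normal
#' distribution narrowed to `width` times and down-shifted by `downshift`
#' times that column's observed SD.
#'
#' @param width SD of the imputation distribution, as a fraction of the
#'   column SD (default 0.3).
#' @param downshift mean shift below the column mean, in column SDs
#'   (default 1.8).
#' @param seed RNG seed.
#' @return an `impute_spec` list.
#' @export
impute_spec <- function(width = 0.3, downshift = 1.8, seed = 1L) {
  if (!(width > 0)) stop("width must be > 0", call. = FALSE)
  if (downshift < 0) stop("downshift must be >= 0", call. = FALSE)
  structure(list(width = width, downshift = downshift, seed = as.integer(seed)),
            class = "impute_spec")
}

#' Impute missing log2 intensities from a left-shifted Gaussian
#'
#' For each sample column with observed mean `mu` and SD `sigma`, every `NA`
#' is replaced by an independent draw from
#' `Normal(mu - downshift * sigma, (width * sigma)^2)`. Observed values are
#' never altered; a fixed seed reproduces the draw exactly.
#'
#' @param logm numeric matrix from [log2_transform()] (`NA` = missing).
#' @param spec an [impute_spec()].
#' @return a complete numeric matrix of the same shape.
#' @export
impute_left_gaussian <- function(logm, spec = impute_spec()) {
  n_obs <- colSums(!is.na(logm))
  if (any(n_obs < 2))
    stop("column(s) with < 2 observed values: ",
         paste(colnames(logm)[n_obs < 2], collapse = ", "), call. = FALSE)
  withr::with_seed(spec$seed, {
    out <- logm
    for (j in seq_len(ncol(logm))) {
      miss <- is.na(logm[, j])
      if (!any(miss)) next
      mu <- mean(logm[, j], na.rm = TRUE)
      sigma <- stats::sd(logm[, j], na.rm = TRUE)
      out[miss, j] <- stats::rnorm(sum(miss),
                                   mean = mu - spec$downshift * sigma,
                                   sd = spec$width * sigma)
    }
    out
  })
}

# one-way ANOVA F for every row of x given a grouping vector; NA for
# zero-total-variance rows, Inf when between-group variance meets zero
# within-group variance
row_anova_f <- function(x, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  n <- ncol(x)
  sizes <- as.vector(table(groups))
  gm <- rowMeans(x)
  group_means <- t(rowsum(t(x), groups)) / rep(sizes, each = nrow(x))
  sst <- rowSums((x - gm)^2)
  ssb <- rowSums(sweep((group_means - gm)^2, 2, sizes, `*`))
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[sst == 0] <- NA_real_
  f
}

#' Multi-group test with permutation-based FDR
#'
#' Computes a one-way ANOVA F statistic per protein and estimates q-values
#' from a null distribution built by `n_perm` random permutations of the
#' sample labels (the same permutation is applied to all proteins within one
#' randomization, preserving protein-protein correlation). The q-value of
#' protein g is the SAM/Tusher-style ratio estimator: the `center` (median
#' by default, as in the original significance-analysis-of-microarrays
#' procedure) over permutations of the per-permutation count
#' `#(F_perm >= F_g)`, divided by `#(F_obs >= F_g)`, clipped to `[0, 1]` and
#' made monotone non-increasing in F (ties broken by input order). The
#' median is robust to null contamination: permuted statistics of truly
#' differential proteins only exceed a large `F_g` in the rare
#' group-preserving permutations, which inflate the mean but not the
#' median. `center = "mean"` gives the pooled-permutation mean variant.
#' Constant rows have an undefined F and are assigned `q = 1`.
#'
#' @param x complete (imputed) numeric matrix, proteins x samples.
#' @param groups cell-type label per column of `x` (>= 2 levels, >= 2
#'   samples each).
#' @param n_perm number of label permutations (default 250).
#' @param q_threshold significance cut-off on q (default 0.01).
#' @param seed RNG seed for the permutations.
#' @param center summary of the per-permutation false-call counts:
#'   `"median"` (default, Tusher-style) or `"mean"`.
#' @return an `anova_result`: a tibble `protein_id`, `F`, `q`, `significant`,
#'   with attributes recording the parameters and estimator variant.
#' @export
permutation_fdr_anova <- function(x, groups, n_perm = 250,
                                  q_threshold = 0.01, seed = 1L,
                                  center = c("median", "mean")) {
  groups <- as.factor(groups)
  center <- match.arg(center)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("need >= 2 samples per group", call. = FALSE)
  if (anyNA(x)) stop("matrix must be complete (imputed)", call. = FALSE)
  n <- ncol(x)
  f_obs <- row_anova_f(x, groups)

  ok <- !is.na(f_obs)
  q <- rep(1, length(f_obs))
  if (any(ok)) {
    fo <- f_obs[ok]
    # per-permutation counts of permuted F >= each observed F
    counts <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        fb <- row_anova_f(x, groups[sample.int(n)])
        fb <- sort(fb[!is.na(fb)])
        length(fb) - findInterval(fo, fb, left.open = TRUE)
      }, integer(length(fo)))
    })
    counts <- matrix(counts, nrow = length(fo))
    false_calls <- if (center == "median") {
      apply(counts, 1, stats::median)
    } else {
      rowMeans(counts)
    }
    obs_sorted <- sort(fo)
    ge_obs <- length(obs_sorted) -
      findInterval(fo, obs_sorted, left.open = TRUE)
    raw <- pmin(pmax(false_calls / ge_obs, 0), 1)
    # monotone non-increasing in F; ties broken by input order
    ord <- order(fo, decreasing = TRUE)
    raw[ord] <- cummax(raw[ord])
    q[ok] <- raw
  }
  out <- tibble::tibble(
    protein_id = rownames(x) %||% as.character(seq_len(nrow(x))),
    F = f_obs, q = q, significant = q < q_threshold
  )
  structure(out,
            class = c("anova_result", class(out)),
            n_perm = n_perm, q_threshold = q_threshold, seed = seed,
            estimator = paste0("per-permutation false-call ", center,
                               " ratio, monotonized (SAM/Tusher-style)"),
            permutation = "unstratified uniform")
}

#' Summarise an ANOVA result
#' @param x an `anova_result`.
#' @param ... unused.
#' @return a one-row tibble of counts and parameters.
#' @method glance anova_result
#' @export
glance.anova_result <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x),
    n_significant = sum(x$significant),
    n_perm = attr(x, "n_perm"),
    q_threshold = attr(x, "q_threshold"),
    estimator = attr(x, "estimator")
  )
}

#' Pairwise per-protein mean log2 intensities for two cell types
#'
#' Coordinates for the classic two-cell-type LFQ scatterplot, computed
#' without imputation: missing values are excluded from each mean, and a
#' protein's coordinate is `NA` when it is entirely missing in that type.
#'
#' @param logm matrix from [log2_transform()] (`NA` = missing).
#' @param groups label per column.
#' @param type_a,type_b the two cell types to compare.
#' @return a tibble `protein_id`, `mean_a`, `mean_b`.
#' @export
pairwise_scatter <- function(logm, groups, type_a, type_b) {
  if (!all(c(type_a, type_b) %in% groups))
    stop("unknown type label", call. = FALSE)
  masked_mean <- function(type) {
    v <- unname(rowMeans(logm[, groups == type, drop = FALSE], na.rm = TRUE))
    v[is.nan(v)] <- NA_real_
    v
  }
  tibble::tibble(
    protein_id = rownames(logm) %||% as.character(seq_len(nrow(logm))),
    mean_a = masked_mean(type_a),
    mean_b = masked_mean(type_b)
  )
}

#' Sample PCA and correlation structure
#'
#' Projects samples on the first two principal components of the
#' protein-centred imputed log2 matrix and computes the full sample-sample
#' Pearson correlation matrix. Replicates of one cell type should correlate
#' more strongly with each other than with other cell types.
#'
#' @param x complete numeric matrix, proteins x samples.
#' @param groups optional label per sample, carried into the scores tibble.
#' @return a list with `scores` (tibble `sample`, `group`, `PC1`, `PC2`),
#'   `var_explained` (length-2 fraction of variance) and `correlation`
#'   (samples x samples Pearson matrix).
#' @export
sample_pca_and_correlation <- function(x, groups = NULL) {
  if (ncol(x) < 2) stop("need >= 2 samples", call. = FALSE)
  if (anyNA(x)) stop("matrix must be complete (imputed)", call. = FALSE)
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  scores <- tibble::tibble(
    sample = colnames(x) %||% as.character(seq_len(ncol(x))),
    group = groups %||% NA_character_,
    PC1 = pc$x[, 1],
    PC2 = if (ncol(pc$x) >= 2) pc$x[, 2] else 0
  )
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, var_explained = ve[1:2], correlation = stats::cor(x))
}
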