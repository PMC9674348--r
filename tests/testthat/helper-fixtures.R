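# Programmatic fixtures shared across test files.

# tiny intensity matrix built by hand
make_tiny_matrix <- function(n_prot = 4, groups = c("Visc", "SubQ", "Brown"),
                             reps = 2, seed = 42) {
  withr::with_seed(seed, {
    samples <- tibble::tibble(
      sample = paste0(rep(groups, each = reps), "_", rep(seq_len(reps), length(groups))),
      group = rep(groups, each = reps),
      replicate = rep(seq_len(reps), length(groups))
    )
    lfq <- matrix(stats::rlnorm(n_prot * nrow(samples), 18, 1),
                  nrow = n_prot,
                  dimnames = list(sprintf("P%02d", seq_len(n_prot)),
                                  samples$sample))
    intensity_matrix(lfq, lfq * 2, samples)
  })
}

# count-matched QC-flag fixture: n_total rows of which n_flagged carry some
# flag (spread over the three flag kinds, positions interleaved)
make_flag_fixture <- function(n_total, n_flagged, seed = 1) {
  withr::with_seed(seed, {
    m <- make_tiny_matrix(n_prot = n_total, reps = 2, seed = seed)
    idx <- sample.int(n_total, n_flagged)
    kind <- rep_len(1:3, n_flagged)
    m$flags$reverse[idx[kind == 1]] <- TRUE
    m$flags$contaminant[idx[kind == 2]] <- TRUE
    m$flags$only_by_site[idx[kind == 3]] <- TRUE
    # a few rows with multiple flags must still be removed exactly once
    m$flags$contaminant[idx[1]] <- TRUE
    m
  })
}

# deterministic 88-tissue atlas holding one canonical-adipokine-like gene
# ("Adipoq") enriched far above 76 tissues but within 4 log2 of the 10
# adipose-adjacent tissues, plus exchangeable background genes
make_adipoq_atlas <- function(n_background = 80, seed = 9) {
  withr::with_seed(seed, {
    n_tissues <- 88
    reps <- 3
    tissues <- c("eWAT", "BAT", sprintf("T%02d", seq_len(n_tissues - 2)))
    near <- sprintf("T%02d", 1:10)        # e.g. mammary gland: lower but n.s.
    cols <- tibble::tibble(
      tissue = rep(tissues, each = reps),
      replicate = rep(seq_len(reps), n_tissues)
    )
    cols$label <- paste0(cols$tissue, "_", cols$replicate)
    genes <- c("Adipoq", sprintf("Bg%03d", seq_len(n_background)))
    expr <- matrix(stats::rnorm(length(genes) * nrow(cols), 7, 0.1),
                   nrow = length(genes),
                   dimnames = list(genes, cols$label))
    expr["Adipoq", cols$tissue %in% c("eWAT", "BAT")] <- 13
    expr["Adipoq", cols$tissue %in% near] <- 10.5          # delta 2.5 < 4
    expr["Adipoq", !cols$tissue %in% c("eWAT", "BAT", near)] <- 5  # delta 8
    expr <- expr + matrix(stats::rnorm(length(expr), 0, 0.05), nrow = nrow(expr))
    tissue_atlas(expr, cols[c("label", "tissue", "replicate")],
                 adipose_tissues = c("eWAT", "BAT"))
  })
}
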