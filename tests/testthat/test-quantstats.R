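test_that("detection filter applies the >=2-in-any-group rule", {
  m <- make_tiny_matrix(n_prot = 2, reps = 3)
  # protein 1: 3/3 in Visc, 0 elsewhere; protein 2: 1/3 everywhere
  m$lfq[] <- 0
  m$lfq[1, m$samples$group == "Visc"] <- 100
  m$lfq[2, m$samples$replicate == 1] <- 100
  kept <- filter_detected(m, detection_filter_spec(2, 3))
  expect_identical(rownames(kept$lfq), "P01")

  # random-missingness fixture vs brute-force per-group counting
  withr::with_seed(3, {
    m2 <- make_tiny_matrix(n_prot = 500, reps = 3)
    m2$lfq[runif(length(m2$lfq)) < 0.5] <- 0
    kept2 <- filter_detected(m2, detection_filter_spec(2, 3))
    oracle_keep <- vapply(seq_len(nrow(m2$lfq)), function(i) {
      any(vapply(unique(m2$samples$group), function(g)
        sum(m2$lfq[i, m2$samples$group == g] > 0) >= 2, logical(1)))
    }, logical(1))
    expect_identical(rownames(kept2$lfq), rownames(m2$lfq)[oracle_keep])
  })

  expect_error(filter_detected(make_tiny_matrix(reps = 1),
                               detection_filter_spec(2, 3)), "group size")
})

test_that("log2 transform maps zeros to NA and keeps values exact", {
  m <- make_tiny_matrix(n_prot = 1, groups = "A", reps = 3)
  m$lfq[1, ] <- c(8, 1, 0)
  lg <- log2_transform(m)
  expect_equal(unname(lg[1, 1:2]), c(3, 0))
  expect_true(is.na(lg[1, 3]))
})

test_that("left-shifted Gaussian imputation matches its stated moments", {
  # column with many observed values and 10,000 missing entries
  withr::with_seed(10, {
    n_obs <- 5000; n_miss <- 10000
    col <- c(rnorm(n_obs, 20, 2), rep(NA_real_, n_miss))
    logm <- cbind(a = col, b = rnorm(n_obs + n_miss, 20, 2))
    sp <- impute_spec(width = 0.3, downshift = 1.8, seed = 77)
    out <- impute_left_gaussian(logm, sp)
    mu <- mean(col, na.rm = TRUE); sigma <- sd(col, na.rm = TRUE)
    imp <- out[is.na(col), "a"]
    se_mean <- 0.3 * sigma / sqrt(n_miss)
    se_sd <- 0.3 * sigma / sqrt(2 * (n_miss - 1))
    expect_lt(abs(mean(imp) - (mu - 1.8 * sigma)), 3 * se_mean)
    expect_lt(abs(sd(imp) - 0.3 * sigma), 3 * se_sd)
    # observed entries untouched; same seed reproduces exactly
    expect_identical(out[!is.na(col), "a"], col[!is.na(col)])
    expect_identical(impute_left_gaussian(logm, sp), out)
  })
})

test_that("imputation handles the no-missing and small-width limits", {
  withr::with_seed(2, {
    logm <- matrix(rnorm(40, 25, 2), 10, 4,
                   dimnames = list(NULL, paste0("s", 1:4)))
    expect_identical(impute_left_gaussian(logm, impute_spec(seed = 1)), logm)
    logm[3, 2] <- NA
    out <- impute_left_gaussian(logm, impute_spec(width = 1e-9, downshift = 0,
                                                  seed = 1))
    expect_equal(unname(out[3, 2]), mean(logm[, 2], na.rm = TRUE),
                 tolerance = 1e-6)
    logm[, 3] <- NA; logm[1, 3] <- 5
    expect_error(impute_left_gaussian(logm, impute_spec(seed = 1)),
                 "< 2 observed")
  })
})

test_that("ANOVA F agrees with the textbook two-pass oracle", {
  withr::with_seed(6, {
    for (rep in 1:3) {
      x <- matrix(rnorm(45), 5, 9)
      groups <- rep(c("A", "B", "C"), each = 3)
      res <- permutation_fdr_anova(x, groups, n_perm = 5, seed = 1)
      oracle <- apply(x, 1, oracle_anova_f, groups = groups)
      expect_equal(res$F, unname(oracle), tolerance = 1e-10)
    }
  })
})

test_that("permutation FDR controls the global null and recovers planted effects", {
  withr::with_seed(21, {
    p <- 1000; groups <- rep(c("A", "B", "C"), each = 3)
    # global null
    xn <- matrix(rnorm(p * 9), p, 9)
    resn <- permutation_fdr_anova(xn, groups, n_perm = 100, seed = 5)
    bound <- 0.01 * p + 3 * sqrt(p * 0.01 * 0.99)
    expect_lte(sum(resn$significant), bound)

    # strong planted effects (8 sigma): high sensitivity, controlled FDP
    x <- matrix(rnorm(p * 9), p, 9)
    shift_type <- sample(c("A", "B", "C"), 100, replace = TRUE)
    for (i in 1:100) x[i, groups == shift_type[i]] <-
      x[i, groups == shift_type[i]] + 8
    res <- permutation_fdr_anova(x, groups, n_perm = 250, seed = 5)
    expect_gte(mean(res$significant[1:100]), 0.95)
    fdp <- sum(res$significant[-(1:100)]) / max(1, sum(res$significant))
    expect_lte(fdp, 0.05)
  })
})

test_that("q-values are monotone in F, tie-symmetric, and 1 for constant rows", {
  withr::with_seed(9, {
    x <- matrix(rnorm(200 * 9), 200, 9)
    x[1, ] <- x[2, ] <- rep(c(0, 4, 8), each = 3)  # identical strong rows
    x[3, ] <- 7                                     # constant row
    groups <- rep(c("A", "B", "C"), each = 3)
    res <- permutation_fdr_anova(x, groups, n_perm = 50, seed = 2)
    expect_identical(res$q[1], res$q[2])
    expect_true(is.na(res$F[3]))
    expect_equal(res$q[3], 1)
    ord <- order(res$F[-3], decreasing = TRUE)
    expect_true(all(diff(res$q[-3][ord]) >= 0))
  })
})

test_that("pairwise means skip missing values exactly as a masked oracle", {
  m <- make_tiny_matrix(n_prot = 3, reps = 3)
  lg <- log2_transform(m)
  lg[1, ] <- rep(5, ncol(lg))
  lg[2, m$samples$group == "Visc"] <- c(NA, 4, 6)
  lg[3, m$samples$group == "Brown"] <- NA
  tbl <- pairwise_scatter(lg, m$samples$group, "Visc", "Brown")
  expect_equal(tbl$mean_a[1], 5)
  expect_equal(tbl$mean_a[2], 5)       # mean of remaining two
  expect_true(is.na(tbl$mean_b[3]))    # fully missing coordinate
  withr::with_seed(14, {
    lg2 <- matrix(rnorm(60), 10, 6)
    lg2[sample(60, 20)] <- NA
    groups <- rep(c("X", "Y"), each = 3)
    tbl2 <- pairwise_scatter(lg2, groups, "X", "Y")
    for (i in 1:10) {
      v <- lg2[i, groups == "X"]
      expected <- if (all(is.na(v))) NA_real_ else mean(v[!is.na(v)])
      expect_equal(tbl2$mean_a[i], expected)
    }
  })
  expect_error(pairwise_scatter(lg, m$samples$group, "Visc", "Nope"),
               "unknown type")
})

test_that("sample PCA and correlations separate well-planted cell types", {
  dup <- matrix(rnorm(100), 50, 2)
  dup <- cbind(s1 = dup[, 1], s2 = dup[, 1], s3 = dup[, 2])
  pc <- sample_pca_and_correlation(dup)
  expect_equal(pc$correlation["s1", "s2"], 1)
  expect_equal(pc$correlation, t(pc$correlation))
  expect_equal(unname(diag(pc$correlation)), rep(1, 3))

  sim <- simulate_cm_matrix(synth_config(n_proteins = 400,
                                         frac_differential = 0.6,
                                         effect_log2 = 4, seed = 31))
  logm <- log2_transform(sim$matrix)
  imp <- impute_left_gaussian(logm, impute_spec(seed = 8))
  res <- sample_pca_and_correlation(imp, sim$matrix$samples$group)
  cm <- res$correlation
  g <- sim$matrix$samples$group
  within <- cm[outer(g, g, "==") & upper.tri(cm)]
  between <- cm[outer(g, g, "!=") & upper.tri(cm)]
  expect_gt(min(within), max(between))
})
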