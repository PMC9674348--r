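test_that("moderated pairwise DE detects planted enrichment and spares nulls", {
  withr::with_seed(19, {
    hits <- logical(20)
    null_flags <- logical(20)
    for (r in 1:20) {
      cfg <- synth_config(n_proteins = 150, n_tissues = 8,
                          atlas_effect_log2 = 6, atlas_rep_sigma = 0.3,
                          n_adipose_genes = 1, seed = 1000 + r)
      sim <- simulate_atlas(cfg)
      de <- pairwise_tissue_de(sim$atlas, "Tissue01")
      planted <- sim$truth$gene[sim$truth$adipose_enriched]
      hits[r] <- de$significant[de$gene == planted]
      null_flags[r] <- any(de$significant[de$gene != planted])
    }
    expect_gte(mean(hits), 0.95)       # delta 6, SD 0.3: detection ~ certain
    expect_lte(mean(null_flags), 0.05) # null genes essentially never called
  })
})

test_that("moderated statistic reduces to the ordinary t when prior df is 0", {
  withr::with_seed(5, {
    sim <- simulate_atlas(synth_config(n_proteins = 60, n_tissues = 5, seed = 2))
    atl <- sim$atlas
    de0 <- pairwise_tissue_de(atl, "Tissue02", prior_df = 0)
    i1 <- which(atl$columns$tissue %in% atl$adipose_tissues)
    i2 <- which(atl$columns$tissue == "Tissue02")
    for (g in sample(rownames(atl$expr), 5)) {
      tt <- t.test(atl$expr[g, i1], atl$expr[g, i2], var.equal = TRUE)
      expect_equal(de0$t[de0$gene == g], unname(tt$statistic), tolerance = 1e-10)
      expect_equal(de0$p[de0$gene == g], tt$p.value, tolerance = 1e-10)
    }
  })
})

test_that("variance shrinkage agrees with an independent empirical-Bayes oracle", {
  skip_if_not_installed("limma")
  withr::with_seed(6, {
    sim <- simulate_atlas(synth_config(n_proteins = 200, n_tissues = 6, seed = 4))
    atl <- sim$atlas
    de <- pairwise_tissue_de(atl, "Tissue03")
    i1 <- which(atl$columns$tissue %in% atl$adipose_tissues)
    i2 <- which(atl$columns$tissue == "Tissue03")
    x1 <- atl$expr[, i1]; x2 <- atl$expr[, i2]
    df <- length(i1) + length(i2) - 2
    s2 <- (rowSums((x1 - rowMeans(x1))^2) + rowSums((x2 - rowMeans(x2))^2)) / df
    sq <- limma::squeezeVar(s2, df = df)
    expect_equal(attr(de, "prior_df"), sq$df.prior, tolerance = 1e-6)
    expect_equal(attr(de, "prior_var"), sq$var.prior, tolerance = 1e-6)
  })
})

test_that("BH adjustment matches the brute-force step-up procedure", {
  # worked example: classic 15 p-value list (Benjamini & Hochberg 1995)
  p_bh95 <- c(0.0001, 0.0004, 0.0019, 0.0095, 0.0201, 0.0278, 0.0298,
              0.0344, 0.0459, 0.3240, 0.4262, 0.5719, 0.6528, 0.7590, 1.0000)
  expect_equal(stats::p.adjust(p_bh95, "BH"), oracle_bh(p_bh95),
               tolerance = 1e-12)
  # at FDR 0.05 the step-up rejects exactly the first four
  expect_equal(which(oracle_bh(p_bh95) < 0.05), 1:4)
  withr::with_seed(8, {
    for (i in 1:5) {
      p <- runif(50)^2
      expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
    }
  })
})

test_that("enrichment scores separate planted from exchangeable genes", {
  withr::with_seed(33, {
    ok_planted <- logical(5); ok_null <- logical(5)
    for (r in 1:5) {
      cfg <- synth_config(n_proteins = 100, n_tissues = 12,
                          atlas_effect_log2 = 6, atlas_rep_sigma = 0.3,
                          n_adipose_genes = 3, seed = 500 + r)
      sim <- simulate_atlas(cfg)
      sc <- enrichment_score(sim$atlas)
      planted <- sim$truth$adipose_enriched
      ok_planted[r] <- all(sc$score_percent[planted] > 80)
      ok_null[r] <- all(sc$score_percent[!planted] < 10)
    }
    expect_gte(mean(ok_planted), 0.95)
    expect_gte(mean(ok_null), 0.95)
  })
})

test_that("enrichment score is monotone in the gene's adipose expression", {
  sim <- simulate_atlas(synth_config(n_proteins = 50, n_tissues = 10,
                                     n_adipose_genes = 1,
                                     atlas_effect_log2 = 3, seed = 21))
  atl <- sim$atlas
  g <- sim$truth$gene[sim$truth$adipose_enriched]
  base <- enrichment_score(atl)$n_enriched[rownames(atl$expr) == g]
  adipose_cols <- atl$columns$tissue %in% atl$adipose_tissues
  for (bump in c(1, 3, 6)) {
    atl2 <- atl
    atl2$expr[g, adipose_cols] <- atl$expr[g, adipose_cols] + bump
    n2 <- enrichment_score(atl2)$n_enriched[rownames(atl2$expr) == g]
    expect_gte(n2, base)
    base <- n2
  }
})

test_that("all enrichment modes behave and errors are raised", {
  sim <- simulate_atlas(synth_config(n_proteins = 40, n_tissues = 6,
                                     atlas_effect_log2 = 6, seed = 3))
  for (mode in c("combined", "eWAT", "BAT", "any")) {
    sc <- enrichment_score(sim$atlas, mode = mode)
    expect_true(all(sc$n_enriched >= 0 & sc$n_enriched <= sc$n_comparisons))
    expect_true(all(sc$score_percent >= 0 & sc$score_percent <= 100))
    expect_equal(unique(sc$n_comparisons), 4)
  }
  # "any" dominates every single-reference mode
  s_any <- enrichment_score(sim$atlas, mode = "any")
  s_comb <- enrichment_score(sim$atlas, mode = "combined")
  expect_true(all(s_any$n_enriched >= s_comb$n_enriched))
  expect_error(enrichment_score(sim$atlas, mode = "liver"), "mode")
  expect_error(pairwise_tissue_de(sim$atlas, "eWAT"), "non-adipose")
})

test_that("relative expression fractions match a naive mean/sum oracle", {
  sim <- simulate_atlas(synth_config(n_proteins = 30, n_tissues = 5, seed = 6))
  atl <- sim$atlas
  rel <- relative_expression(atl)
  tissues <- sort(unique(atl$columns$tissue))
  frac <- as.matrix(rel[tissues])
  expect_equal(unname(rowSums(frac)), rep(1, nrow(frac)), tolerance = 1e-9)
  for (g in rownames(atl$expr)[1:5]) {
    naive <- vapply(tissues, function(tn)
      mean(2^atl$expr[g, atl$columns$tissue == tn]), numeric(1))
    naive <- naive / sum(naive)
    expect_equal(unname(frac[rel$gene == g, ]), unname(naive), tolerance = 1e-12)
  }
  # single-tissue expresser gets fraction ~1 and that top tissue
  atl2 <- atl
  atl2$expr["Gene0001", ] <- 0
  atl2$expr["Gene0001", atl2$columns$tissue == "BAT"] <- 20
  rel2 <- relative_expression(atl2)
  expect_equal(rel2$BAT[rel2$gene == "Gene0001"], 1, tolerance = 1e-4)
  expect_equal(rel2$top_tissue[rel2$gene == "Gene0001"], "BAT")
  # uniform gene: fractions 1/T, ties broken by tissue-name order
  atl2$expr["Gene0002", ] <- 5
  rel3 <- relative_expression(atl2)
  expect_equal(unname(as.matrix(rel3[rel3$gene == "Gene0002", tissues])[1, ]),
               rep(1 / 5, 5))
  expect_equal(rel3$top_tissue[rel3$gene == "Gene0002"], tissues[1])
})

test_that("t-SNE embedding is reproducible, keeps duplicates close, separates planted profile groups", {
  withr::with_seed(41, {
    n_half <- 60
    profA <- c(rep(0.23, 4), rep(0.02, 4))
    profB <- c(rep(0.02, 4), rep(0.23, 4))
    X <- rbind(
      matrix(rep(profA, n_half), n_half, byrow = TRUE),
      matrix(rep(profB, n_half), n_half, byrow = TRUE)
    ) + matrix(runif(2 * n_half * 8, 0, 0.01), 2 * n_half, 8)
    X <- X / rowSums(X)
    rownames(X) <- sprintf("g%03d", seq_len(2 * n_half))
    X[2, ] <- X[1, ]  # exact duplicate pair

    emb <- embed_tsne(X, perplexity = 30, max_iter = 400, seed = 9)
    expect_identical(embed_tsne(X, perplexity = 30, max_iter = 400, seed = 9),
                     emb)
    xy <- as.matrix(emb[c("TSNE1", "TSNE2")])
    spread <- max(dist(xy))
    expect_lt(sqrt(sum((xy[1, ] - xy[2, ])^2)), 0.05 * spread)
    lab <- rep(1:2, each = n_half)
    expect_gt(oracle_silhouette(xy, lab), 0.5)
  })
  expect_warning(embed_tsne(matrix(runif(40), 10, 4), perplexity = 30,
                            max_iter = 10, seed = 1), "perplexity")
  expect_error(embed_tsne(matrix(c(NaN, runif(15)), 4, 4), perplexity = 2,
                          max_iter = 10, seed = 1), "non-finite")
})

test_that("atlas CSV round-trip preserves the container", {
  sim <- simulate_atlas(synth_config(n_proteins = 25, n_tissues = 5, seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tissue_atlas(sim$atlas, path)
  back <- read_tissue_atlas(path)
  expect_equal(back$expr, sim$atlas$expr, tolerance = 1e-9)
  expect_equal(back$adipose_tissues, sim$atlas$adipose_tissues)
})
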