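---
title: "Methods: quantitative secretome analysis and adipokine candidate discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative secretome analysis and adipokine candidate discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secretomics)
```

## The analysis model

`secretomics` treats adipokine discovery as three independent evidence
layers joined on gene symbols:

1. **Secretion into conditioned medium (CM).** Label-free MS intensities of
   proteins secreted by cultured adipocytes of several depots (visceral,
   subcutaneous, brown), three biological replicates each. LFQ intensities
   are comparable across samples for one protein; iBAQ intensities are
   comparable across proteins within a sample and proxy molar abundance.
2. **Tissue specificity.** A log2 expression atlas (genes x tissues x
   replicates) in which the two adipose depots serve as the reference for
   pairwise differential-expression tests against every other tissue.
3. **Presence in circulation.** A set of gene symbols detected in the
   nascent serum proteome.

A candidate adipokine must be CM-detected, adipose-enriched with a score
strictly above 80%, and serum-detected.

## Stage-by-stage assumptions and parameters

### QC exclusion and detection filtering

Reverse-database hits, potential contaminants and proteins identified only
by a modification site are dropped as the union of the three flags; the
flag convention is the literal `"+"` token of MaxQuant tables. A protein
enters quantitative analysis when it has at least `min_detected = 2`
quantified replicates (of `per_group_size = 3`) in **at least one** cell
type — the filter is deliberately per-group so a protein secreted by a
single depot is retained.

### Imputation (width 0.3, downshift 1.8)

Label-free MS missingness is missing-not-at-random: low-abundance values
drop out preferentially. Missing log2 values in sample column *j* are
therefore drawn from a *left-shifted* Gaussian
\(N(\mu_j - 1.8\,\sigma_j,\ (0.3\,\sigma_j)^2)\), where \(\mu_j, \sigma_j\)
are the observed mean and SD of that column. The convention is column-wise
(per sample), because the width/downshift parameters are defined relative to
each sample's own intensity distribution; a global variant would mix
samples of different depth. Observed values are never altered, and the draw
is reproducible from `impute_spec(seed = )`. A column needs at least two
observed values; fewer is an error, not a silent fallback.

### Permutation-FDR ANOVA (q < 0.01, 250 randomizations)

Differential secretion across cell types is tested with the one-way ANOVA F
statistic per protein. The null distribution comes from `n_perm = 250`
random permutations of the sample labels, the same permutation applied to
all proteins within a randomization so protein–protein correlation survives
under the null. The q-value of protein *g* is the ratio estimator

\[ q_g = \frac{\operatorname{median}_b\, \#\{F^{(b)}_{perm} \ge F_g\}}
             {\#\{F_{obs} \ge F_g\}} , \]

clipped to [0, 1] and made monotone non-increasing in F (ties broken by
input order). Two design choices deserve justification:

* **Median, not mean, of the per-permutation false-call counts.** This is
  the original significance-analysis-of-microarrays convention. It matters
  because permutations do not delete true effects: a permutation that
  happens to keep a differential protein's samples grouped reproduces its
  large F and, under a mean, contaminates the null tail enough to prevent
  any q from falling below the 0.01 threshold when many proteins are truly
  differential. Such group-preserving permutations are rare (for a 3x3
  design, a specific triple stays together in ~3.6% of permutations), so
  the per-permutation count at a large F is 0 in the vast majority of
  permutations and the median is robust to the contamination while the mean
  is not. The estimator variant is recorded in the result's metadata, and
  `center = "mean"` is available.
* **Unstratified uniform permutations.** Whether the original analyses
  balanced permutations across cell types is not stated anywhere we could
  rely on; the plain uniform scheme is used and flagged in metadata.

Constant (zero-variance) rows have no defined F and receive q = 1.

### Clustering and annotation

Rows are z-scored (population SD, matching the ±1.2247 closed form for a
3-sample row) and clustered by complete-linkage agglomeration on Euclidean
distance, cut to exactly k = 4 clusters. The distance metric is a package
choice — only the linkage is conventionally fixed — and is recorded in the
result attributes. Cluster labels are renumbered by descending mean z-score
in a reference cell type (the first group by default) so label order is
deterministic and heatmap-like. Term overrepresentation is an explicit
one-sided hypergeometric tail with BH adjustment; it is a documented,
offline stand-in for web-service annotation tools, not a claim of
reproducing their term lists.

### Secretion rules

The classifier applies the published thresholds literally: classical
secretion requires signal-peptide score > 0.5 **and** at most one predicted
transmembrane segment; non-classical requires score > 0.6 **and** signal
score ≤ 0.5 (the two routes are therefore mutually exclusive by
construction); GPI anchoring requires specificity > 99; predicted
localization matches `"extracellular"` case-insensitively. All inequalities
at 0.5 / 0.6 / 99 are strict. Missing predictor outputs contribute `FALSE`
rather than erroring, because real predictor tables have dropouts; a
completeness report (`annotation_completeness()`) makes the dropouts
visible.

### Tissue enrichment score

For each non-adipose tissue *t*, each gene is tested for lower expression
in *t* than in the adipose reference with a two-sample statistic whose
residual variance is shrunk by empirical Bayes: per-gene pooled variances
\(s^2_g\) (df *d*) are modelled as \(s_0^2 F_{d, d_0}\), the prior
\((d_0, s_0^2)\) estimated by moment-matching on \(\log s^2_g\) using
digamma/trigamma identities (trigamma inverted by Newton iteration). The
moderated variance is \((d_0 s_0^2 + d s^2_g)/(d_0 + d)\) with
\(d_0 + d\) degrees of freedom; at \(d_0 = 0\) the statistic reduces to the
ordinary t-test (verified numerically in the tests), and when the
log-variance spread is no larger than its sampling noise the prior df is
infinite and the common variance is the arithmetic mean. A comparison
counts as enriched when log2FC (adipose − other) exceeds 4 **and** the
BH-adjusted p (adjusted across genes within that tissue pair, mirroring a
per-contrast DE analysis; a flag switches to global adjustment) is below
0.05. The score is \(100 \cdot n_{enriched} / (T - 2)\).

The adipose reference is a `mode` parameter: `"combined"` (default, both
depots' replicates pooled — the worked numerical example in the acceptance
suite uses this reading), `"eWAT"`, `"BAT"`, or `"any"` (a tissue counts
when significant against any of the three references). The wording behind
this choice is ambiguous; all four modes are computed rather than guessing
intent, and the default is documented here.

### Relative expression and t-SNE

Relative expression divides each tissue's mean **linear-scale** expression
(mean of \(2^{x}\) over replicates) by the gene's summed expression across
tissues, because the source atlas normalization is linear; a flag averages
on the log scale instead. Ties in the top tissue break by tissue-name
order. The 2-D map uses exact (non-Barnes-Hut) t-SNE written in-package —
the conventional external implementation is not part of the guaranteed
runtime — with perplexity 30, 1000 gradient iterations, early exaggeration
12 for the first 100 iterations, learning rate 200 and a 0.5→0.8 momentum
switch at iteration 250; the perplexity is auto-reduced with a warning when
fewer than 3·perplexity+1 rows are supplied. Coordinates are reproducible
under a fixed seed and are only ever assessed through invariant properties
(duplicates embed together, planted profile groups separate); no test or
criterion depends on coordinate values.

### Candidate intersection

Gene symbols are upper-cased before joining (collisions are an error listing
the offending symbols), the report covers the union of the three evidence
layers in alphabetical order, and the 80% threshold is strict. Multi-protein
genes are expected to be resolved to one symbol upstream (OR over proteins).

## The synthetic world

`synth_config()` states the world once:

* log2 LFQ baselines ~ N(25, 2) per protein with replicate SD 0.5 — typical
  magnitudes for MaxQuant LFQ output;
* half the proteins carry a +4 log2 shift in one random cell type (strong,
  as depot-specific secretion differences are in real CM data);
* missingness is value-level and logistic in the latent log2 intensity,
  `plogis(17.6 − 0.8·x)`: ~50% missing at x = 22, ~8% at the centre of the
  intensity distribution, matching the left-censored look of LFQ matrices.
  Value-level (not protein-level) missingness is what makes a ≥2-of-3
  replicate filter meaningful;
* iBAQ = LFQ × a per-protein lognormal scalar, since iBAQ is only used for
  ranking and summation, never inference;
* the atlas has 88 tissues × 3 replicates (so T − 2 = 86 comparisons),
  baselines ~ N(7, 1) with replicate SD 0.3, and 5 genes planted with +6
  log2 adipose enrichment;
* each artifact draws from its own RNG substream (fixed offsets from the
  master seed), so adding an artifact never shifts another.

What the generator does **not** emulate: peptide-level quantification,
retention-time structure, correlated missingness across replicates of one
protein, batch effects, or the heavy-tailed contaminant background of real
CM. A green end-to-end test therefore establishes that the pipeline's logic
and statistics behave as specified under the stated noise model — not that
real-data funnel counts would be reproduced.

## Numerical choices and degenerate inputs

* Zero intensities and empty cells both decode to "missing"; file row order
  is preserved everywhere; no silent sorting.
* A fully-flagged table excludes to a valid 0-row matrix.
* F-statistic ties during monotonization, top-tissue ties, and iBAQ ranking
  ties all break deterministically (input order / name order).
* The trigamma inversion runs Newton steps to relative tolerance 1e-8 with
  the standard large/small-argument shortcuts.
* All randomness flows from explicit seeds in spec objects; nothing reads
  global RNG state (`withr::with_seed` preserves the caller's RNG).

## Known limitations

* The permutation-FDR design has an intrinsic power ceiling at small
  replicate numbers: with 3 replicates per group the null F distribution
  has (2, 6) degrees of freedom, whose tail is heavy enough that even exact
  F p-values with BH adjustment cannot call moderate (≈5 SD) single-group
  shifts at q < 0.01 with high sensitivity. This is a property of the
  design, not the estimator; the test suite documents it by asserting high
  sensitivity only at effect sizes (≈8 SD) where the design supports it.
* DAVID-style annotation enrichment and the external secretion predictors
  are consumed as inputs, never re-executed; conclusions about "predicted
  secreted" proteins inherit whatever versions produced the score table.
* The enrichment score treats tissues as exchangeable units; adipose-embedded
  tissues (e.g. mammary gland) legitimately depress scores of true
  adipokines, which is why the candidate threshold is 80% rather than 100%.
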