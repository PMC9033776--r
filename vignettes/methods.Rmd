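---
title: "Methods: synergy-aware differential expression for a 2x2 perturbation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synergy-aware differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syndge)
```

## Scope and design

`syndge` analyzes bulk RNA-seq from a 2x2 design crossing a diagnosis
contrast (CTRL vs SZ) with a drug treatment (vehicle vs the BET
inhibitor JQ1), with unbalanced group sizes (4/3/4/3 by default). The
package's core question is the *additive versus synergistic* behavior of
the combined condition, so the pipeline is built around a single
four-cell linear model from which every comparison — including the
additive prediction and the interaction — is a contrast. This vignette
records the model, the tunable parameters, the synthetic-data generator
used for validation, and the design decisions taken where the design was
genuinely open.

## Preprocessing

**Filtering.** Genes with a count strictly greater than 15 in at least 2
samples are retained. The strict inequality is the default (`strict =
TRUE`); a `>=` variant is exposed because "over 15" is sometimes read
inclusively. Filtering is idempotent and order-preserving.

**Normalization.** TMM scaling factors (trimmed mean of M-values; 30%
trim on log-ratios, 5% on abundance, precision weights, reference sample
by upper-quartile proximity) are computed by `edgeR::calcNormFactors`
behind the `tmm_factors()` surface; factors are rescaled to geometric
mean 1 and define effective library sizes.

**log2-CPM.** `log2((count + 0.5) / (effective libsize + 1) * 1e6)`. The
0.5 prior and the `+1` denominator are the conventional choices; they
keep the transform finite at zero counts and monotone in the count.

## The linear model

The four cells are coded by indicators (no intercept), so every printed
comparison is a single contrast vector `c`:

| contrast | c over (CTRL_VEH, SZ_VEH, CTRL_JQ, SZ_JQ) |
|---|---|
| SZ_vs_CTRL | (-1, 1, 0, 0) |
| JQ_vs_CTRL | (-1, 0, 1, 0) |
| SZJQ_vs_CTRL (combinatorial, C) | (-1, 0, 0, 1) |
| ADDITIVE (A) | (-2, 1, 1, 0) |
| SYNERGY (S) | (1, -1, -1, 1) |

`S = C - A` holds *identically* — it is the same linear functional — so
the decomposition is asserted to 1e-10 on every dataset as a
self-consistency check, and the additive effect carries a proper
contrast SE (`sqrt(c' (X'WX)^-1 c)`), not a sum of per-contrast SEs.

**Precision weights.** Per-gene residual standard deviations from
unweighted fits are square-rooted and smoothed against average log2
count by `lowess` (span 0.5). Each fitted value is mapped through the
trend by linear interpolation, clamped at the trend's ends so
extrapolation cannot blow up, and the weight is the interpolated value
to the power -4. When effective library sizes are supplied the trend is
indexed on the log-count scale so a sample's depth shifts its predicted
log-count. With equal settings this reproduces `limma::voom` weights to
~1e-13, which the test suite uses as an independent cross-check; the
implementation itself is self-contained.

**Moderation.** The prior `(d0, s0^2)` is estimated by moment matching
of `log s_g^2` to a scaled-F model: the bias and spread of the log
variances are inverted through digamma/trigamma (Newton inversion of the
trigamma function). Posterior variances are the convex combination
`(d0 s0^2 + d s^2) / (d0 + d)`; moderated t uses `d0 + d` df. Forced
limits are supported (`prior_df = 0` gives ordinary t; `Inf` shrinks to
the common variance) because they pin down the estimator's two ends.
No variance trend and no robust down-weighting are applied — the
simplest published moderation variant; both would be extensions, not
defaults, since nothing in the target analysis specifies them.

**FDR.** Benjamini–Hochberg step-up via `stats::p.adjust`. Two-sided
p-values throughout.

## Synergy categories

The global threshold `tau` is the scalar mean over genes of the
moderated synergy-contrast SE — a literal reading of "the average
standard error in all samples". A per-gene alternative can be had by
passing `tau` explicitly. Genes with `S > tau` show positive synergy,
`S < -tau` negative synergy. The direction clause — "the additive model
shows the same or no direction" — is implemented as sign agreement with
`A_g`, including `A_g = 0`: `more_up` requires `S > tau` and `A >= 0`,
`more_down` requires `S < -tau` and `A <= 0`, everything else is
`as_predicted`. Consequences worth knowing:

* Raising `tau` is monotone: genes can only move into `as_predicted`.
* For a *pure* interaction gene the true additive effect is 0, so the
  estimated `A` is a coin flip around zero and is strongly negatively
  correlated with the estimated `S` under this design (about -0.8).
  The "more" categories therefore capture roughly half of pure
  interaction genes even at large effect sizes; detection of the synergy
  signal itself (`|S|` beyond `tau` with the planted sign) is near 1 at
  `|bS| = 1.5`. This is a property of the classification rule, not of
  the estimator, and the test suite measures both quantities separately.
* Under a purely additive simulation the "more" fraction stays small
  (~2-3% at defaults), well under the 10% bound the tests assert.

The SE entering `tau` is taken from the synergy contrast (the quantity
being thresholded); "calculated for all samples" is ambiguous and this
is the interpretation adopted.

**Heatmap support.** `cluster_for_heatmap()` performs
Euclidean/complete hierarchical clustering of rows and columns, with
k-means pre-aggregation (k = 100, fixed seed) when more than 1000 rows
are clustered — the pre-aggregation trigger used by common heatmap
workflows; only the >1000 trigger is fixed by the analysis being
emulated, so k = 100 is a package default.

## Gene-set enrichment

`camera_test()` is the competitive test with an inter-gene-correlation
variance-inflation factor `VIF = 1 + (m - 1) rho`: moderated t
statistics are mapped to normal-equivalent scores, and each set is
compared to the rest of the universe by a two-sample t statistic on
`G - 2` df whose in-set variance term is inflated by the VIF. The fixed
default `rho = 0.01` is the conventional small positive value; the exact
setting used in the emulated analysis is unspecified. The implementation
matches `limma::cameraPR` to 1e-12 in the cross-check test. With
`rho = 0` and a large set it reduces to an ordinary two-sample test.

`hypergeometric_ora()` is the upper-tail hypergeometric test of a hit
list against the background of all *expressed* genes (the
filter-surviving universe — hits outside the universe are an error, not
silently dropped), BH-adjusted and ranked by `-log10(p)`.

## Co-expression modules

Unsigned adjacency `|cor|^beta` with the default `beta = 7`;
`pick_soft_threshold()` reports the signed scale-free fit R² and mean
connectivity across candidate powers. The topological overlap matrix

    TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)

is turned into the dissimilarity `1 - TOM` and clustered with average
linkage. Three module-detection choices are deliberate:

* **Static cut at a fixed height (0.9) on the dissimilarity scale**, not
  at a quantile of merge heights. On a noise network all dissimilarities
  concentrate near 1, so any quantile-of-heights cut would manufacture
  large clusters; a fixed-height cut sends pure noise entirely to grey
  while planted blocks (whose TOM dissimilarity sits far below 1) merge
  early. The full dynamic-hybrid tree cut is out of scope; the static
  cut plus the membership filter below stands in for it.
* **Minimum module size 30**; smaller clusters go to the reserved
  "grey" (unconnected) label, and colors are assigned in size order.
* **Module-membership (kME) filter.** After eigengene merging, members
  whose correlation with their module eigengene is not significant at
  `alpha = 0.001` (two-sided Student test, two passes) are reassigned to
  grey. At 14 samples the null distribution of a gene-eigengene
  correlation is wide (sd ~ 0.28), and hundreds of background genes
  compete for membership, so a Bonferroni-scale level is appropriate;
  this is the standard cleanup practice for weighted co-expression
  modules.

Module eigengenes are unit-norm leading principal-component scores of
the standardized in-module expression, signed to correlate nonnegatively
with the module mean profile; modules whose eigengene dissimilarity
`1 - cor` falls below the merge height 0.17 are merged iteratively.
Module–trait association uses weighted Pearson correlation (uniform
weights by default — the weighting scheme behind the emulated analysis
is unstated, and uniform weights reduce exactly to ordinary Pearson)
with the Student asymptotic p-value on `n - 2` df. `n_modules` counts
non-grey modules and `n_modules_total` adds grey when present, so both
of the module-count conventions in circulation ("18 plus grey" vs "19")
are reported without arbitration.

## Promoter co-occupancy

Promoters are `[tss - 1000, tss + 1000)` in 0-based half-open (BED)
coordinates, clamped at zero, strand-recorded but strand-invariant
(whether windows should be collapsed per gene or kept per transcript
TSS is unspecified; one region per TSS record is produced). RPKM is
`count * 1e9 / (length_bp * libsize)`, and the co-occupancy statistic is
Spearman's rho with midranks and the large-sample t approximation for
the p-value. Reproducing the published BRD4/H2A.Zac correlation level
requires the external ChIP-seq data and is out of scope; the simulator
plants a known rank correlation instead.

## The synthetic-data generator

`simulate_counts()` emulates the study conditions: 4/3/4/3 samples,
negative-binomial counts with mean
`(L_s/1e6) * 2^(b0 + bD[SZ] + bT[JQ] + bS[SZ][JQ])` and dispersion
`phi(mu) = 0.05 + 2/mu` (a decreasing biological-CV trend typical of
bulk RNA-seq; the emulated analysis is silent on the count
distribution), log-normal library sizes (log-mean `ln 1e7`, log-sd 0.3),
and baseline log expression `N(2.5, 1.5)` on the natural-log CPM scale —
chosen so a realistic minority of genes falls below the expression
filter. Effects are independent Bernoulli draws per class (so genes can
carry several effects; class "mixed"), with random sign and magnitude
`|N(mean, sd)|`.

Correlated blocks for module testing load each block gene on one shared
per-sample latent factor. Two calibration details matter:

* the loading is `lambda_g^2 = v_g * rho / (1 - rho)` against the gene's
  own NB log-noise variance `v_g`, so the pairwise correlation of block
  genes is approximately `block_cor` at *every* expression level (a
  fixed latent sd would silently weaken low-expression blocks);
* the realized factor is standardized across the samples — the factor is
  defined only up to scale, and without this ~10% of 14-sample draws
  produce a low-variance factor whose block vanishes in-sample.

`simulate_gene_sets()` builds a categorized collection (eight neural-
flavored category labels partitioning the sets, mirroring a curated
resource of several hundred sets) with optional planted enrichment at a
stated odds ratio. `simulate_promoter_occupancy()` draws two count
vectors from a shared bivariate-normal log signal; the latent Pearson
correlation is set by the Gaussian-copula inversion
`rho_P = 2 sin(pi rho_S / 6)` so the *Spearman* correlation lands on
target, and counts are the deterministic rounding of the scaled
log-normal signal so that `target_rho = 1` yields exactly 1.

What the generator does *not* emulate: batch effects beyond library
size, UMI/single-cell noise, read-level artifacts, gene length bias, and
correlated effect sizes across classes. Passing tests therefore
demonstrate correctness of the statistical machinery under a clean NB
world, not robustness to every artifact of real libraries.

## Numerical choices and degenerate inputs

* WLS is solved per gene by Cholesky of `X'WX`; singular weighted normal
  equations are an error, as is a rank-deficient design.
* The trigamma inversion uses Newton steps with closed-form asymptotic
  starting points; `evar <= 0` falls back to `d0 = Inf` (all variances
  equal), whose posterior is exactly `s0^2`.
* The interpolated trend is floored at 1e-6 before the ^-4 power so
  weights stay finite; scaling all weights by a constant provably leaves
  t and p unchanged.
* Merge heights are made monotone (`cummax`) before the static cut to
  absorb floating-point jitter in ties.
* A singleton module's eigengene is its standardized profile; constant
  genes are rejected up front in network construction.
* Library-size sums are coerced to double before RPKM to avoid integer
  overflow on deep libraries.

## Problem sizes used in validation

The test suite and the acceptance script run at desk scale, chosen to
keep every Monte-Carlo bound comfortably estimable: 2000-gene
simulations for type-I error (20 replicates) and planted-interaction
recovery (10 replicates), 1000-gene universes with two 50-gene blocks
for module recovery (ARI over seeds; measured mean 0.96, min 0.90 over
ten seeds during development), 5000 promoters for the rank-correlation
calibration (within +/-0.05 of the 0.88 target), and <=30-gene matrices
for brute-force TOM and WLS oracles.

## Known limitations

* The static cut plus kME filter approximates, but is not, the
  dynamic-hybrid tree cut; very close or nested modules may resolve
  differently.
* Moderation without a variance trend can under-shrink when the
  mean-variance trend is strong after weighting; the weights are doing
  that job here.
* The "more" categories inherit the direction-clause coin-flip for pure
  interaction genes discussed above; consumers who want raw interaction
  detection should threshold `|S|` against `tau` directly.
* Covariate residualization ahead of module detection is a hook, not a
  fitted model: the covariates used by the emulated analysis are not
  stated, so none are applied by default.
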