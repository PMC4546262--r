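---
title: "Methods: subtype centroids and the risk-of-recurrence score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subtype centroids and the risk-of-recurrence score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamror)
```

## Scope

`pamror` implements a complete, trainable version of the PAM50-style
breast-cancer intrinsic-subtype classifier and the associated
risk-of-recurrence (ROR) score for digital count data: control-probe QC
and normalization, centroid training by hierarchical clustering with
Monte-Carlo cluster-significance testing, single-sample nearest-centroid
classification, a ridge-penalized Cox ROR model, 0–100 scaling with
node-negative risk groups, and the survival-analysis machinery used to
evaluate such models. A synthetic-data generator produces
subtype-structured cohorts with proportional-hazards outcomes so every
stage can be exercised and tested without clinical data. Real clinical
cohorts — and any numbers computed from them — are outside the package's
scope.

## Normalization model

Raw probe counts are mapped to normalized log2 expression in two additive
steps:

1. **Reference-sample correction.** For gene $g$ in sample $s$,
   $x_{gs} = \log_2(c_{gs} + q) - \log_2(r_g + q)$, where $r_g$ is the
   per-gene count of an in-vitro-transcribed reference pool covering all
   58 targets (50 classifier genes + 8 housekeepers) and $q$ is a
   pseudocount (default 1; 0 is allowed when counts are strictly
   positive).
2. **Housekeeper centring.** The per-sample arithmetic mean of the
   housekeeper values of $x$ is subtracted — equivalently, division by the
   geometric mean of the housekeeper ratios. After this step the
   housekeeper mean of every sample is exactly 0, which makes downstream
   classification invariant to global library-size scaling of a sample's
   counts.

Because both steps are additive in log space they commute; the order is
fixed as reference-first. When no reference profile is supplied (the
configuration used for feasibility-style runs with 5 housekeepers), only
housekeeper centring is applied.

**QC.** Positive-control linearity is the $R^2$ of
$\log_2(\text{count}+q)$ against $\log_2(\text{expected concentration})$
over the six titration probes. Background is estimated from the eight
negative controls as mean $+\,2\cdot$SD (sample SD, $n-1$ denominator);
this mean-plus-two-SD rule is the conventional digital-counting
background estimate — the multiplier is configurable. A sample is flagged
low-signal when its housekeeper geometric mean does not exceed
background; flagged samples fail QC, operationalizing the exclusion of
low-signal samples before training. Both thresholds are configurable
because only the *intent* (exclude low-signal samples) is fixed by the
assay description, not a numeric rule.

**%CV.** Reproducibility summaries use the coefficient of variation on
the linear scale ($2^x$), the convention behind "%CV" in platform
studies; genes with fewer than two replicates or zero mean are reported
missing and excluded from the median.

## Centroid training

Training reproduces the published workflow's structure:

* **Clustering input.** Normalized log2 expression of the classifier
  genes, median-centred per gene. Median-centring affects only the
  clustering/labeling view; the Z-scaler of the final model (below) is
  fit on non-centred normalized data.
* **Distance and linkage.** Pearson correlation distance
  $d = 1 - \rho$ with average-linkage (UPGMA) clustering. The UPGMA
  routine is implemented in the package with an explicit deterministic
  tie-break (lowest pair of original sample indices) so dendrograms are
  reproducible; it is cross-checked in the tests against both
  `stats::hclust` and a brute-force re-averaging oracle.
* **Cluster significance.** Each node's two-way split is tested against
  a single multivariate Gaussian null in the style of SigClust. The
  statistic is the 2-means cluster index (within-cluster SS over total
  SS) of the observed split. The null's diagonal covariance uses the
  node's sample-covariance eigenvalues hard-thresholded from below at a
  background noise variance estimated by the scaled MAD of all matrix
  entries; because the cluster index is rotation invariant only the
  spectrum matters. For each of `n_sim` null datasets the minimal
  2-means index is found by a compiled Lloyd search with random
  restarts, and $p$ is the fraction of null indices at or below the
  observed one. The published workflow names the testing package but not
  its settings, so all null-model knobs (`n_sim`, restarts, background
  variance) are arguments. Monte-Carlo checks in the test suite show the
  test is conservative under a single-Gaussian null (empirical type-I
  error well below nominal at both $\alpha = 0.05$ and
  $\alpha = 0.001$), which costs a little power but never manufactures
  clusters.
* **Traversal and labeling.** The dendrogram is traversed top-down:
  significant splits ($p < \alpha$, default $\alpha = 0.001$) are
  descended, and the maximal coherent nodes where descent stops become
  candidate clusters. Candidates of at least `min_cluster_size` samples
  are scored against a marker map — mean centred expression of expected
  high markers minus expected low markers (basal keratins for
  Basal-like; ERBB2/GRB7/FGFR4 for HER2-enriched; the
  estrogen-associated module for both luminal subtypes, which are split
  by the proliferation module) — and greedily assigned to the four
  subtypes by decreasing score, requiring a positive score. Leftover
  clusters (e.g. non-tumor, reduction-mammoplasty-like groups) stay
  unlabeled. If Luminal B receives no cluster while two clusters both
  best-match Luminal A, the one with strictly higher proliferation is
  relabeled Luminal B; failing that, training aborts with an explicit
  "training set insufficient" error rather than guessing.
* **Z-scaler and centroids.** A per-gene Z transform
  ($\mu_g, \sigma_g$ with the $n-1$ denominator) is fit on the tumor
  training samples — unlabeled (non-tumor) clusters are excluded, the
  default resolution of an ambiguity in the source workflow — and then
  frozen: new samples are always scaled with the stored parameters,
  never re-centred on their own cohort. Each centroid is the per-gene
  arithmetic mean of its cluster's Z-scaled prototypes (median available
  via `summary = "median"`); the mean is the default because the source
  workflow does not name the summary and the mean is deterministic and
  matches the Gaussian working model.

## Classification

A sample is assigned the subtype whose centroid has the maximum Pearson
correlation with its Z-scaled 50-gene vector. The call is a pure
function of the sample and the frozen model — no cohort quantities enter
— so a sample classifies identically alone or in any batch, the property
that distinguishes a fixed clinical model from research classifiers that
re-centre each dataset. Correlation makes the call invariant to positive
affine transforms of the input. Exact ties are broken by the fixed order
LumA, LumB, Her2E, Basal with a warning (they are measure-zero on real
data). There is deliberately no Normal-like centroid: inclusion of
non-tumor tissue is a pathology/macrodissection concern, not a
classifier concern.

## ROR model

Per sample, the features are the four centroid correlations
$\rho_{1..4}$, the proliferation score $P$ (arithmetic mean of the
Z-scaled expression of an 11-gene cell-cycle subset; the packaged
default list is from the prior PCR-based ROR-P work since the reduced
list used by the commercial assay is supplement-only — it is fully
configurable in the codeset), and a binary tumor-size indicator $T$
($T = 0$ for ≤ 2.0 cm, $T = 1$ for > 2.0 cm; missing sizes exclude the
sample from size-dependent scoring with a message).

Coefficients are learned by ridge-penalized Cox regression: maximize the
partial log-likelihood (Breslow ties by default, Efron behind a flag)
minus $\lambda \lVert \beta \rVert^2 / 2$, via `survival::coxph` with a
ridge penalty term. The size term enters the ridge fit as an ordinary
covariate (the phrasing "additive terms" is ambiguous; including it in
the joint fit is the simpler and stated default). Because the source
never reports how $\lambda$ was chosen, `lambda = "auto"` selects it by
k-fold cross-validated partial likelihood (Verweij–van Houwelingen) over
a log-spaced grid with a seed-fixed fold assignment; a numeric
$\lambda$ bypasses CV. Covariates are standardized inside the penalty by
default (coefficients reported on the original scale) — documented
because it changes the ridge solution.

The raw score is the linear predictor
$\sum_k a_k \rho_k + bP + cT$. A linear scaling fitted on the designated
scaling cohort maps its minimum raw score to 0 and maximum to 100;
out-of-range scores of later samples clamp to $[0, 100]$ with a warning.
Node-negative risk groups use the published strict cutoffs — low below
40, high above 60 — with boundary values (exactly 40 or 60) assigned to
the intermediate band, and any non-node-negative input rejected because
no cutoffs are defined for it here. The reduced **46-gene variant**
removes BIRC5, CCNB1, GRB7 and MYBL2 from the correlation panel and the
proliferation subset; `compare_variants()` trains both variants on one
cohort and reports the paired $R^2$, slope and intercept.

## Evaluation machinery

* **Endpoints.** RFS counts local/regional/distant recurrence and
  breast-cancer death as events (a breast-cancer death with no recorded
  recurrence is an event at the death date); contralateral disease and
  other-cause death censor. DRFS is not defined in the source text, so
  the package's documented default counts distant recurrence and
  breast-cancer death as events, censoring local/regional/contralateral;
  DSS counts breast-cancer death. All three are configurable through
  `derive_endpoint()`.
* **Concordance.** Harrell's C over all determinable pairs: the
  shorter time must end in an event (a tied time with exactly one event
  is usable; two tied events or two censored times are not); tied scores
  get half credit. The implementation is an explicit vectorized
  $n^2$ pair enumeration and is required by the tests to match both a
  literal double-loop oracle and `survival::concordance`.
* **Bootstrap.** Subjects are resampled with replacement (default
  1,000 replicates), the C-index of every model recomputed per
  replicate, and percentile intervals reported per model and for all
  pairwise differences; replicates with no comparable pairs are dropped
  and counted. Percentile (not BCa) intervals are the documented choice.
* **Hazard ratios.** Unpenalized Cox fit with subtype as a categorical
  covariate against a reference subtype (LumA); optional truncation at a
  horizon (e.g. 10 years) is administrative censoring, with events at
  exactly the horizon still counting. Subtypes with zero events are
  reported with an infinite upper CI and a warning rather than dropped
  silently.
* **Kaplan–Meier / log-rank.** Product-limit curves per group via
  `survival::survfit`, unstratified log-rank with $k-1$ degrees of
  freedom; tests require equality with a hand product-limit oracle on
  small instances.
* **ICC.** Two-way mixed-effects, absolute-agreement, single-measure
  ICC from ANOVA mean squares — the standard variant for
  platform-reproducibility studies; no installed package provides it, so
  the mean-squares formula is implemented directly and checked against
  `aov` in the tests.

## Synthetic-data generator

The generator is first-class, tested code. It emulates the statistical
structure the pipeline assumes, with defaults chosen once as a realistic
mid-size training study:

* **Templates.** Five 50-gene log2 templates (four subtypes + a
  non-tumor profile) with the marker-block structure described above;
  contrasts of roughly ±1.5–2.5 log2 units between defining modules,
  comparable to the separation seen between intrinsic subtypes on
  expression panels. Genes outside the named modules get a small fixed
  template-specific offset so templates differ across the whole panel.
* **Counts.** Classifier counts are lognormal around
  $2^{9 + \text{template}}$ (≈ 500 counts at baseline) with per-gene
  Gaussian log2 noise (default SD 0.4) and a lognormal per-sample
  library-size factor (sdlog 0.2) so housekeeper normalization is
  non-trivially exercised; housekeepers are fixed baselines times
  library size with 5 % jitter; negative controls are Poisson (mean 8);
  positive controls are Poisson around concentration × 30. A lognormal
  noise model was chosen over negative binomial for analytic
  transparency — the real platform's noise model is not described in the
  source — and all counts are floored at 1. Non-tumor samples come from
  the fifth template and are never labeled with a subtype.
* **Outcomes.** Event times are exponential with hazard
  $h_0 \exp(\text{subtype log-HR} + b_P P + c_T T)$; defaults
  $h_0 = 0.05$/yr, subtype log-HRs $(0, \log 3, \log 5, \log 3)$
  mirroring the qualitative ordering reported for intrinsic subtypes
  (HER2-enriched worst, Luminal A reference), $b_P = 0.5$,
  $c_T = 0.6$. Independent exponential censoring is calibrated by
  root-finding to hit the configured censoring rate (default 0.3) in
  expectation, accurate to within ±5 % at n ≥ 500. Tumor sizes are
  lognormal (median 2 cm) so both size categories occur; event types are
  drawn consistently with the endpoint rules.

**What passing on synthetic data does and does not show.** The generator
matches the pipeline's working assumptions (Gaussian log-expression,
proportional hazards, independent censoring, well-separated subtypes).
Passing tests therefore demonstrate internal correctness — formulas,
invariances, determinism, recovery of known truth — not clinical
performance. Real FFPE count data have heavier tails, probe-level
artefacts, correlated noise and cohort structure the generator does not
model, and headline clinical quantities (cohort hazard ratios, C-index
values, the 0.997 variant agreement) are properties of specific patient
cohorts that synthetic data cannot and should not reproduce exactly.

## Numerical choices and degenerate inputs

* Gene identifiers are case-sensitive and matched exactly; aliasing is
  out of scope.
* Zero-variance genes abort scaler fitting by name; constant sample
  vectors abort distance computation and classification.
* The UPGMA tie-break, the classification tie-break, and all Monte-Carlo
  seeds make every stochastic stage bit-reproducible under a fixed seed.
* Models serialize to versioned JSON with 17 significant digits, enough
  to round-trip IEEE doubles exactly, and embed a codeset hash so a
  model cannot be applied to a mismatched panel; unknown schema versions
  error instead of being coerced.
* Problem sizes in the tests and the acceptance script (cohorts of
  ~300–500 tumors, 1,000–2,000 Monte-Carlo replicates, n = 2,000
  recovery fits) were chosen as the smallest sizes at which the checked
  quantities are statistically stable.

## Known limitations

* The packaged housekeeper list and proliferation subset are documented
  defaults for lists the source text does not enumerate; analyses that
  need the exact commercial panel must supply their own codeset.
* Node-positive risk cutoffs, historical ROR variants (ROR-S/ROR-C),
  chemotherapy-benefit prediction, platform correction for external
  microarray data, and comparator clinical models are out of scope.
* The cluster-significance test is conservative; at very small training
  sizes it may refuse to find four subtypes, which surfaces as the
  explicit "training set insufficient" error.
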