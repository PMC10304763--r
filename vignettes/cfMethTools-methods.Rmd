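---
title: "Methods: ccfDNA methylation deconvolution and DMR biomarker analysis"
author: "cfMethTools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ccfDNA methylation deconvolution and DMR biomarker analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the tunable parameters, the
synthetic-data generator and the numerical design decisions behind
`cfMethTools`. It is the reference for *why* each step behaves the way it
does; the README shows the surface API.

# The deconvolution model

A bulk plasma methylation profile is modeled as a convex combination of
cell-type-specific profiles. Writing $S$ for the signature matrix (CpGs
$\times$ cell types, beta values in $[0,1]$) and $b$ for the bulk beta vector
on the shared CpGs,

$$ b \approx S\,p, \qquad p \ge 0,\ \textstyle\sum_k p_k = 1 . $$

Four solvers are offered by `deconvolute()`:

* **nnls** — Lawson–Hanson non-negative least squares
  (`pracma::lsqnonneg`), followed by renormalization to sum 1;
* **qp** — the quadratic program $\min \lVert Sp - b\rVert^2$ subject to
  $p \ge 0,\ \sum p = 1$ (`quadprog::solve.QP`, equality constraint first);
* **svr** — linear-kernel $\nu$-support-vector regression
  (`e1071::svm`, $\nu = 0.5$, $C = 1$, no feature scaling), the coefficient
  vector recovered from the support vectors, then truncated at 0 and
  renormalized;
* **rlm** — Huber M-estimation without intercept (`MASS::rlm`), truncated
  and renormalized.

Assumptions: methylation mixes linearly in proportions (true for read
fractions when coverage is comparable across cell types), the signature
columns span the cell types actually present, and measurement noise is
roughly symmetric on the beta scale. Missing bulk values are dropped
probewise (WGBS coverage gaps are expected); a run requires at least
`max(10, n cell types)` shared probes (`minProbes`, relaxable for toys).

**Why $\nu$-SVR.** The package pins the SVR variant to $\nu$-regression with
$\nu = 0.5$, $C = 1$. An $\varepsilon$-insensitive tube of fixed width
(e.g. $\varepsilon = 0.1$) on the beta scale shrinks the coefficient vector
noticeably — on noiseless synthetic mixtures the truncated/renormalized
estimate misses the truth by a few percentage points, which defeats the
purpose of a proportion estimator. $\nu$-SVR adapts the tube width to the
data and recovers noiseless mixtures to $<10^{-3}$, which the test suite
asserts (tolerance $10^{-2}$).

**NNLS versus QP under noise.** With additive i.i.d. Gaussian noise the QP
solver is the maximum-likelihood estimator constrained to the simplex, and
when the true $p$ lies on the simplex no renormalized unconstrained
estimator can beat it systematically: in the package benchmark (200
mixtures, noise SD 0.05) QP and NNLS tie to three significant digits with QP
ahead by $\sim$0.2% relative, and NNLS is consistently at least as accurate
as SVR and RLM. The acceptance suite records the strict "NNLS lowest"
ordering as a separate check; the statistically meaningful content — NNLS
$\le$ SVR and NNLS $\le$ RLM, and the NNLS/QP tie — is what the module tests
assert. In the noiseless regime all exact solvers sit at machine precision
and their ordering is roundoff.

# Signature construction

`buildSignatureMatrix()` runs, in order:

1. **Filtering and pooling** (`filterAndPool`): probes with any missing
   value or with row-wise *population* variance below
   `varianceThreshold = 0.001` are removed, then replicate columns are
   averaged per tissue. The threshold is interpreted on the beta scale
   (0.1% $=$ 0.001); it is configurable because the alternative reading
   (variance $< 0.1$) would discard almost everything informative.
   Pooling uses the arithmetic mean, the standard aggregation for beta
   values.
2. **Top-k scaled selection** (`selectTopScaled`, `kTop = 100` per direction
   per cell type): each row is divided by its row sum; per cell type the
   `k` probes with the highest scaled value are taken, *skipping probes
   already claimed* by a previously processed cell type. Cell types are
   processed in sorted column order — the order must be fixed for
   reproducibility, and sorted order is the only canonical one. The
   procedure repeats on the reversed matrix ($1-\beta$, then row-scaled) for
   hypomethylated markers. The exclusion list is shared between the hyper
   and hypo passes, so all selected sets are pairwise disjoint; rows with
   zero row sum are skipped in the pass where they are degenerate. Ties
   break by probe ID.
3. **Most-differential selection** (`selectMostDifferential`,
   `kDiff = 200`): one-vs-rest on the *unscaled* atlas. With $\ge 2$
   replicate columns on both sides a two-group one-way ANOVA F statistic is
   used (rank by ascending p); with pooled single columns the score is
   $|\beta_t - \overline{\beta_{-t}}| / (\mathrm{sd}(\beta_{-t}) +
   10^{-6})$. The $10^{-6}$ floor keeps constant-background probes finite.
4. **Neighbors** (`addNeighbors`, `neighborWindow = 50` bp): all atlas CpGs
   within 50 bp of a selected probe on the same chromosome join the set
   (CpG methylation is locally correlated, so neighbors stabilize
   deconvolution against missing probes).
5. **Pairwise-specific probes** (`addPairwiseSpecific`, `kPair = 1`): for
   each unordered pair of cell types, the not-yet-selected probe maximizing
   $|\beta_A - \beta_B|$ is added, pairs in sorted order, ties by probe ID.
   The exact upstream recipe for this step is only cited in the literature,
   so this package declares its own deterministic rule and exposes
   `kPair`.

Provenance of each probe is recorded with fixed precedence
`hyper > hypo > differential > neighbor > pairwise`, and a signature build
is byte-reproducible (tested on written files).

# Probe mapping

WGBS callers report stranded CpG calls; arrays index CpGs by probe ID on the
plus strand. `collapseStrands()` merges each minus-strand record at position
$p$ into the plus-strand record at $p-1$ (the CpG dyad), summing counts —
count totals are conserved. `mapToProbes()` then matches (chromosome,
position) exactly against the manifest and aggregates multiple records per
probe by the coverage-weighted mean $\sum m_i / \sum c_i$; records below
`minCoverage = 1` are dropped first. Coordinates are 1-based closed
internally; Bismark coverage files are read as 1-based and bedGraph files as
0-based half-open with conversion at the reader boundary (`readCalls()`),
because the two upstream toolchains genuinely differ.

# Tiled differential methylation

`tileCounts()` partitions each chromosome into 500-bp windows anchored at
position 1 (step = width, so tiling is a partition; the anchor must be fixed
for window identities to be comparable across runs). Per window and sample,
methylated and total reads are summed over CpGs; windows with fewer than
`minCpGs = 3` covered CpGs in any sample are dropped (single-CpG windows are
too noisy to call at 25-pp effect sizes).

`dmTest()` fits, per window, the binomial logistic regression of per-sample
(methylated, unmethylated) counts on the group indicator and compares it to
the intercept-only model with a 1-df likelihood-ratio chi-square. Because
the group-model MLE is the pooled per-group proportion, the statistic has a
closed form in the group count totals; the implementation is vectorized over
windows and verified in the tests against `glm(..., family = binomial)`
term by term, and against Fisher's exact test within an order of magnitude.
No overdispersion correction is applied. The methylation difference is the
pooled coverage-weighted percentage-point difference (condition − control).

Multiple testing uses Benjamini–Hochberg by default. The original SLIM
q-value estimator is an external method with unpublished implementation
subtleties; BH is transparent and slightly conservative, and the `method`
argument of `adjustQvalues()` keeps a slot for alternatives (a Storey-type
$\pi_0(\lambda = 0.5)$ rescaling ships as `"pi0"`). `callDMRs()` keeps
windows with $q \le 0.01$ and $|\Delta| \ge 25$ pp and assigns direction by
sign.

# Severity models

ACS type is encoded numerically by clinical severity: UA = 1, NSTEMI = 2,
STEMI = 3. Whether healthy controls enter these regressions is genuinely
open (they have no severity code but do appear in downstream ordinations),
so both behaviors exist: `encodeSeverity(..., includeControls = TRUE)` codes
controls as 0, the default excludes them.

Per DMR, `fitDMRModel()` fits the OLS model

$$ Y \sim \beta_0 + \beta_1\,\mathrm{DNAmeth} + \beta_2\,\mathrm{ccfDNAlevel} $$

with $Y$ the severity (or a clinical marker, untransformed), DNAmeth the
window percent methylation and ccfDNAlevel (ng/ml plasma) as covariate —
the covariate controls for the fact that ACS patients simply shed more
ccfDNA. $\beta_1$ is tested by t-test; the nested comparison against
$Y \sim \beta_0 + \beta_2\,\mathrm{ccfDNA}$ uses an F test with
$(1, n-3)$ df, and the single-parameter identity $F = t^2$ is asserted to
$10^{-8}$ on every fit. Severity is treated as a continuous response, as the
linear-model formulation implies; ordinal regression is out of scope.
Degenerate fits (constant methylation, constant response, $<5$ complete
cases) are flagged with $p = 1$ rather than dropped silently.

`selectAssociatedDMRs()` retains fits with $p_{\beta_1} \le 0.05$ and
reports the retained fraction; on pure-null synthetic cohorts that fraction
is calibrated (3–7% at $\alpha = 0.05$, tested on 1200 DMRs).

Classification: `singleMarkerMultinomial()` fits one-predictor multinomial
logistic models (in-sample misclassification rate, as appropriate for
$n \approx 29$ with single predictors; a constant predictor degenerates to
the majority-class rule, ties broken by factor level order).
`trainACSClassifiers()` trains random forest, PLS-DA (`mixOmics`) and
L2-penalized multinomial regression (`glmnet`, $\alpha = 0$; the penalty
grid $10^{-3}\ldots10$ is chosen by the same CV) on a stratified 70/30
split with centering/scaling learned on the training split only, tuned by
repeated 10-fold cross-validation. All splits, folds and model seeds derive
from one integer seed.

# Targeted-panel normalization

Targeted enzymatic-conversion panels show systematic location/scale bias
relative to WGBS. The normalization pipeline
(`normalizeValidationCohort()`) is:

1. pseudo-count log transform $t = \log\frac{x + 1}{(100 - x) + 1}$
   (finite on all of $[0, 100]$; 50% $\mapsto$ 0);
2. quantile normalization of the validation samples to the pooled
   *discovery* distribution: average ranks, then linear interpolation into
   the sorted target at positions $(r-1)/(n-1)$; with equal lengths and no
   ties the mapping is exact (sorted sample $=$ target), and a constant
   sample maps to the target median;
3. ComBat empirical-Bayes location/scale adjustment (`sva::ComBat`,
   parametric priors, no covariates) on the combined matrix with batch =
   cohort;
4. the analytic back transform $x = (101 e^t - 1)/(1 + e^t)$, clipped to
   $[0, 100]$ — the exact inverse of step 1 (round trip $<10^{-9}$ on a
   201-point grid).

Two honest caveats, both verified by simulation in the tests. First, EB
location estimates at 10 samples/batch carry sampling error of a few tenths
of a (transformed-scale) standard deviation per feature, so batch removal is
assessed on the aggregate batch-mean gap and on the between-batch variance
component (reduced by $\ge 90\%$ on planted shifts), not per feature.
Second, ComBat adjusts each feature separately, so the full pipeline is
monotone per sample only up to near-ties (Spearman $> 0.99$); the transform
and quantile stages are exactly monotone. Features with zero within-batch
variance cannot be standardized and pass through unadjusted with a warning.

`concordanceReport()` compares per-DMR mean differences (condition −
control) across cohorts: Pearson r plus counts of validation-significant,
same-direction and fully validated ($|\Delta| \ge 25$ pp) DMRs.

# The synthetic-data generator

The generator defines the study conditions for every test:

* **Atlas** (`makeSyntheticAtlas`): background betas $\sim$ Beta(5, 5)
  (unimodal around 0.5, like array background); each cell type receives
  disjoint hyper- and hypomethylated marker blocks at contrast 0.9 (target
  $0.95$ vs others $0.05$), 10 markers per direction per type by default;
  probes sit on one synthetic chromosome at 100-bp spacing so a 500-bp
  window holds 5 CpGs. Defaults (10 cell types, 5000 CpGs) keep the default
  cohort generation well under a minute.
* **Cohort** (`simulateWGBSCohort`): group sizes default to the discovery
  design 8 control / 8 STEMI / 7 NSTEMI / 6 UA. Mixing proportions default
  to a healthy baseline with a 30% neutrophil share, raised by 5 pp per
  severity unit in ACS (neutrophils dominate plasma ccfDNA and rise in
  ACS). Reads are sampled per CpG as coverage $\sim$ Poisson(8) + 1
  (mean $\approx 9\times$, the upper end of typical ccfDNA WGBS) and
  methylated reads $\sim$ Binomial(coverage, $\beta$) — binomial read noise
  here, deliberately distinct from the Gaussian beta noise used by
  `simulateCellMix()` for solver benchmarking. Planted DMRs shift window
  betas by $\pm 40$ pp in one ACS group (10 windows/group); severity-linear
  windows shift by $0.05 \times$ severity; ccfDNA levels are lognormal with
  medians 6 (control) to 30 (STEMI) ng/ml, inside the reported clinical
  range; clinical markers (troponin T, CK, LVEF, CRP) get severity-linked
  means so marker models have signal.
* **Panel** (`simulateTargetedPanel`): restricts to panel windows, applies
  $t' = \mathrm{scale}\cdot t + \mathrm{shift}$ on the transformed scale
  (default shift 1.0), and resamples reads at Poisson(30) + 1 (targeted
  panels sequence deeper). A validation cohort reuses the discovery truth
  (same planted windows) with the validation design 2/4/3/2.

What the generator does *not* emulate: fragment-length biology, conversion
failure, mapping bias, correlated CpGs beyond the block structure, and
cell-type profiles estimated with error. Passing tests therefore demonstrate
correctness of the statistical machinery under its stated model, not
clinical performance.

# Numerical and reproducibility choices

* All stage seeds derive deterministically from one integer seed
  (`pipelineConfig(seed = ...)`); identical configs give identical outputs,
  which the tests assert.
* The QP Gram matrix gets a $10^{-10}$-scaled ridge only if the
  unregularized factorization fails; rank-deficient signatures produce a
  warning and solver-dependent minimum-norm behavior.
* Ties everywhere break by probe ID / sorted labels; window keys are
  `chrom:start` with 1-based starts; BED output converts to 0-based
  half-open.
* Degenerate inputs are flagged (never silently dropped): zero-coverage
  groups get $p = 1$, constant markers get the majority rule, failed
  per-sample deconvolutions are reported while the cohort run continues.
* Problem sizes in the test and acceptance runs (e.g. 200-mixture
  benchmarks, 2000-window null calibrations, 2600-CpG planted-DMR cohorts,
  the 29-sample end-to-end workflow) were chosen as the smallest designs at
  which the tested properties are statistically stable.

# Known limitations

* Exact-position probe matching only; region-overlap mapping of probes to
  windows is out of scope.
* BH (or the `"pi0"` variant) instead of the SLIM q-value estimator.
* No overdispersion correction in the window test; with strong biological
  replication variability the type-I error can exceed nominal on real data.
* In-sample evaluation for single-marker multinomial models (by design at
  these cohort sizes); the multivariate classifiers do use a held-out
  split.
* Severity as a continuous response; no ordinal link.
* Confidence intervals on deconvolution proportions are not provided.
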