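---
title: "metaboflag: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metaboflag: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboflag)
options(metaboflag.log_level = "ERROR")
```

## The data model

metaboflag analyzes feature-level LC-MS metabolomics data through three
tab-separated interchange formats, and nothing else:

* **wide table** — features in rows, samples in columns, a unique feature ID
  per row, optional `mz` (Da) and `rt` (minutes) annotation columns;
* **design table** — one row per sample: sample ID, treatment group, run
  order, batch and any other covariates;
* **flag table** — an ID column plus binary 0/1 indicator columns.

Every QC and statistical tool takes a (wide, design) pair and emits flag or
result TSVs, so arbitrary tool chains compose through files alone. Missing
intensities are empty cells on disk (`NA`/`NaN` accepted case-insensitively)
and `NA` in memory. After `align_tables()` the canonical sample order is the
design-file order; all tools are order-invariant in their results, which the
test-suite checks by permuting inputs.

## Pre-processing

**Blank feature filtering.** The limit of detection of a feature is
estimated from blank (background) samples as
$LOD = \bar{x}_{blank} + k \cdot s_{blank}$ with $k = 3$ by default; a
feature is flagged within a biological group when its group mean falls below
$m \cdot LOD$ (multiplier $m = 1$). This is the standard blank-based LOD
construction; $k$ and $m$ are exposed because laboratories calibrate them
differently. With a single blank value the sd term is taken as zero; a
feature absent from all blanks has $LOD = 0$ and is never flagged.

**Threshold flags.** A feature is flagged within a group when *strictly more
than 50%* of the group's samples fall below the user's intensity threshold.
Missing cells count as below threshold, because missingness in MS intensity
data overwhelmingly means "below detection" rather than "not measured".

**Normalization and re-scaling.** An optional per-sample division by the
sample's mean, median or sum over features, followed by a per-feature
scaling with feature mean $m$ and sample standard deviation $s$ (always the
$n-1$ denominator): centering $x-m$, autoscaling $(x-m)/s$, Pareto
$(x-m)/\sqrt{s}$, range $(x-m)/(\max-\min)$, level $(x-m)/m$, and VAST
$\frac{x-m}{s}\cdot\frac{m}{s}$, which down-weights unstable features.
Degenerate features (zero $s$, range or mean where the method divides by
them) are set missing and reported rather than raised as errors, so one flat
feature cannot abort a pipeline.

**Log and g-log.** $glog_\lambda(x) = \log_b\!\big(\tfrac{x + \sqrt{x^2 +
\lambda}}{2}\big)$ with base 2, 10 or $e$. At $\lambda = 0$ this is exactly
$\log_b x$ (since $(x + \sqrt{x^2})/2 = x$ for $x > 0$), and that is the
default; $\lambda$ is in squared-intensity units and must be chosen by the
user because its variance-stabilizing value depends on the instrument's
error model.

**Imputation.** All methods work within the treatment group: group
mean/median replacement; KNN over samples (Euclidean distance on
co-observed features, scaled to a per-feature RMS so overlaps of different
sizes compare; neighbors must observe the feature; unweighted mean of the
$k$ nearest, $k$ clipped below the group size with a warning); and
stochastic draws from per-feature-per-group fits — Normal draws truncated at
zero via the inverse CDF, Poisson rates fitted on rounded intensities (the
Poisson option is intended for count-like data; rounding is a documented
approximation). KNN neighbors are samples rather than features because the
sample profiles, not the feature profiles, carry the group structure the
imputation should respect. Stochastic methods are seeded; observed cells are
never altered.

## Quality control

**Retention-time flags.** Per feature, the CV of RT across samples and the
RT range ($\max - \min$). The top `cv_percentile`% (default 10) by CV are
flagged, ties broken by feature order so the count is exactly
$\lceil p\% \cdot n \rceil$; features whose range exceeds the absolute
threshold (default 0.2 min) are flagged separately, and the combined flag is
the OR. The "absolute" criterion is interpreted as the RT range because it
is the simplest per-feature statistic in minutes; the threshold is an
exposed flag.

**Run-order regression.** Per feature, OLS of intensity on run order with a
two-sided t-test of zero slope; flags at the nominal levels 0.05 and 0.01.
Degenerate cases follow explicit conventions: a constant feature has slope 0
and $p = 1$ (no evidence of drift); an exact linear trend has zero residual
variance and $p = 0$; features with fewer than 3 usable points are skipped
with a `flag_poor_data`. The implementation is a closed-form vectorized OLS;
`stats::lm` serves as the independent oracle in the tests.

**Bland-Altman.** For each within-group (or user-specified) sample pair the
per-feature difference $d$ is regressed on the per-feature mean $a$; a
feature is flagged in the pair when any of three standard influence
diagnostics fires: $|$studentized residual$| > t_{0.975,\,n-3}$,
$|DFFITS| > 2\sqrt{2/n}$, or Cook's $D > 4/n$. These are the textbook
regression-diagnostic cutoffs; all three are exposed. Pairs sharing fewer
than 4 features are skipped. Per sample, flagged features are counted across
pairs; the binary per-sample flag marks counts above the mean + 2 sd of all
counts — a package choice, since a count threshold has to come from
somewhere and the counts' own spread is the only scale available without
replicate-level assumptions.

**CV and magnitude flags.** CV flags mark features at or above the
$(100-p)$-th percentile of the CV distribution (boundary ties all included,
so the count can exceed the nominal $p\%$ — the opposite tie rule from RT
flags, where an exact count is the documented contract). Magnitude flags
count digits before the decimal point; a feature is flagged when the
within-group digit-count spread reaches `digit_gap` (default 2 orders of
magnitude), the report lists the 50 widest spreads by default, and each
sample is scored by how many of its features deviate from the group's modal
digit count.

**Distances.** Within each group with center $y$ (per-feature mean) and
per-feature variances $\sigma_i^2$:
$$SED(x, y) = \sqrt{\sum_i \frac{(x_i - y_i)^2}{\sigma_i^2}}, \qquad
MD(x, y) = \sqrt{(x-y)^\top \Sigma^{-1} (x-y)}.$$
With more features than samples the sample covariance $S$ is singular, so
the Mahalanobis tool uses the penalized estimate
$\Sigma(\rho) = (1-\rho)S + \rho\,\mathrm{diag}(S)$; `auto` picks the
smallest $\rho$ on a 0.01 grid whose condition number is at most $10^6$. At
$\rho = 1$, or whenever $S$ is diagonal, PMD reduces exactly to SED (a
test-suite identity). Squared distances to the center are compared against
$\chi^2$ quantiles with df equal to the number of features used, at
confidence levels 0.95/0.975/0.99 — the chi-square reference is exact for
independent Gaussian features with known variance and approximate otherwise,
which is why three levels are reported instead of one verdict. Features with
missing values or zero variance within a group are excluded from that
group's sums and logged; singleton groups are skipped.

## Univariate statistics

One- and two-group t-tests (pooled variance; paired analysis via
within-pair differences), a permutation test (same pooled t-statistic, group
labels permuted jointly across samples, add-one estimator
$p = (1 + \#\{|t^*| \ge |t|\})/(1 + B)$ so $p$ is never 0; exhaustive
enumeration available for small designs), fixed-effects ANOVA with
covariates and optional factor interactions, and Kruskal-Wallis with midrank
tie correction. Zero-variance conventions mirror the run-order tool.
Missing values are deleted casewise per feature. Significance flags are
fixed at 0.05/0.01/0.001.

ANOVA per-factor F-tests come from the sequential (Type I) decomposition of
`stats::anova`; for the single-factor designs that dominate metabolomics
practice every decomposition coincides, and for multi-factor models the
sequential table is reported explicitly rather than silently re-weighted.
Pairwise contrasts of the primary factor are linear contrasts on the fitted
coefficients with the pooled residual MSE (so with covariates they are
adjusted mean differences); contrast p-values are raw — multiple-testing
adjustment is its own composable tool (`adjust_pvalues`: Bonferroni, BH,
BY), matching the suite's "everything chains through files" model. Volcano
output plots $-\log_{10} p$ against the difference of group means (medians
for Kruskal-Wallis).

## Multivariate tools

PCA is SVD on the column-centered samples-by-features matrix
(`stats::prcomp`), components ordered by explained variance. PLS-DA is a
hand-written NIPALS PLS1 on the autoscaled matrix with a 0/1 group response
(group coding by sorted label so swapping labels only flips score signs);
NIPALS was chosen over SIMPLS because for a single response the two
coincide in exact arithmetic and NIPALS is the simpler reference
implementation. LDA wraps `MASS::lda` with the subspace dimension capped at
(number of groups − 1). Hierarchical clustering is centroid linkage on
squared Euclidean distances (`stats::hclust`); centroid linkage can invert
merge heights, so inversions are counted and logged and dendrogram heights
are made monotone only for display. Random-forest importance is
`randomForest`'s mean decrease in Gini impurity; SVM classification wraps
`e1071::svm` and reports resubstitution accuracy on the training set (by
design — an honest generalization estimate needs the cross-validation path).
LASSO/elastic-net selection wraps `glmnet` penalized logistic regression per
unordered group pair: 100 lambdas spanning 4 decades below the all-zero
solution, lambda chosen by minimum mean cross-validated deviance (no 1-SE
rule, to keep the selected set's size monotone in alpha in practice),
selection = nonzero coefficients at that lambda.

Classification and penalized tools autoscale features by default (exposed
flag) because distance- and penalty-based methods are scale-sensitive and
raw intensities span orders of magnitude. Cross-validation, where offered
(PLS-DA and LDA component counts, SVM cost), is 5-fold stratified — 5×5
nested for double CV — seeded, and only permitted for sample sizes above
100; below that the tools refuse rather than return optimistically unstable
fold estimates.

## Synthetic data

`generate_synthetic()` is the package's study-condition generator, not a
test shim: Gaussian intensities around a common baseline, a leading block of
features with additive group mean shifts, a trailing block with linear
run-order drift, MCAR dropout at a fixed rate, and an optional blank-sample
block at a low intensity level. Defaults (10 samples/group, unit noise) are
ordinary pilot-study dimensions. It reproduces bit-identically under a seed.
What it deliberately does not emulate: heavy-tailed and heteroscedastic
intensity error, intensity-dependent (MNAR) missingness, correlated feature
blocks from shared pathways, and batch structure. Passing tests therefore
demonstrate correctness of the statistical machinery under its stated
assumptions, not robustness to every pathology of real spectra.

Validation problem sizes were chosen to exercise the asymptotics that matter
while staying desk-scale: 2000 features × 20 samples for null
type-I-error checks of the run-order tool (binomial 99% CI at both nominal
levels), 1000 features for flag-fraction checks, 20 seeded repetitions of
an n = 40/group, 52-feature design with two features shifted by 2 sd for
elastic-net recovery, and 10 seeds for random-forest rank stability.

## Numerical choices and degenerate inputs

* Sample standard deviations use the $n-1$ denominator everywhere.
* m/z and RT match windows are closed intervals, with a $10^{-9}$ guard so
  a feature sitting exactly on the boundary is never lost to float rounding;
  one-to-many matches are kept and tallied, never resolved silently.
* Permutation p-values can never be 0 (add-one estimator); exhaustive mode
  includes the observed assignment, bounding $p$ below by $1/\binom{n}{n_1}$.
* Flag files serialize as bare `0`/`1` integers; round-trips are identity.
* Zero-variance features: excluded (and logged) from distance tools,
  resolved by the stated $p$-conventions in the test tools, set missing by
  the scalers.

## Limitations

Feature-level input only (no raw spectra, peak picking or alignment);
fixed-effects models only; the modulated-modularity clustering companion
tool and NMR-specific normalizations (e.g. PQN) are out of scope. The
chi-square distance cutoffs and the Bland-Altman per-sample flag are
screening heuristics, not calibrated tests; the flags exist to direct a
scientist's eye, and the filtering decision is deliberately left to the
`drop_flagged` step.
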