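---
title: "Mapping directional epistasis from multi-phenotype combinatorial RNAi screens"
author: "episcan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping directional epistasis from multi-phenotype combinatorial RNAi screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episcan)
```

# The experimental design and the model

`episcan` analyses template–query combinatorial RNAi screens: every *target*
gene is co-depleted with every *query* gene, each gene silenced by two
sequence-independent dsRNA designs, so that each gene pair is measured four
times (the 2 × 2 reagent grid). Automated imaging condenses each
double-knockdown well into a vector of quantitative phenotypic features
(cell number, mitotic index, cell area, texture descriptors, …). The
central data object is therefore a five-dimensional tensor indexed by
(target, target design, query, query design, feature), the
`ScreenTensor` class.

Genetic interactions are defined against a multiplicative null: without an
interaction, the double-knockdown phenotype is the product of the two
single-knockdown effects. After a variance-stabilising transformation the
model becomes additive,

$$ y_{tq} \;=\; m \;+\; a_t \;+\; b_q \;+\; \pi_{tq} \;+\; \varepsilon, $$

per feature and reagent combination, where $m$ is the feature intercept,
$a_t$ and $b_q$ are the single-gene (main) effects of the two reagents and
$\pi_{tq}$ — the *π-score* — is the interaction term. A nonzero π means the
double knockdown deviates from the expectation formed from the two single
knockdowns; its sign distinguishes aggravating from buffering deviations,
per phenotype.

The directional layer is the package's distinctive step. A symmetric
interaction says nothing about which gene acts on which. But with many
phenotypes, π is a *vector* over features, and its geometry is informative:
when the interaction vector is parallel (or antiparallel) to one gene's
main-effect vector, the double knockdown amplifies (or dampens) *that
gene's* phenotype specifically — evidence that the other gene acts upstream
of it. `episcan` fits, for each pair,

$$ \pi \;=\; \alpha\, a \;+\; \beta\, b $$

with no intercept (π and the effect vectors are centred, residual-scale
quantities), quantifies by analysis of variance which fraction of the π
sum of squares each gene explains, and calls a directed edge A → B when A
explains almost nothing and B explains almost everything. The sign of the
coefficient on the downstream gene's vector gives the edge sign:
alleviating (negative — loss of A blunts B's phenotype) or aggravating
(positive).

# Stage by stage

## Variance-stabilising transformation

Raw image-derived features have noise whose spread grows with the signal.
The transform used is $g(x) = \operatorname{asinh}(x/\lambda_f)$ with one
cofactor $\lambda_f$ per feature: linear around zero (slope
$1/\lambda_f$), logarithmic for $x \gg \lambda_f$, anchored at $g(0) = 0$,
smooth, strictly increasing, and defined for negative values without
clipping. The closed form makes the inverse exact
(`inverseVst()` round-trips to within $10^{-10}$ relative error), which
the synthetic generator relies on to emit raw-scale values.

The cofactor is fitted per feature by a deterministic grid search
(`estimateVstParams()`): 50 logarithmically spaced candidates spanning
$[10^{-3}, 10^{3}] \times \mathrm{median}(|x|)$, choosing the candidate
that minimises the absolute Spearman correlation between the absolute
difference and the mean of paired observations (replicates or the two
dsRNA designs). This directly operationalises "spread independent of
signal". Two consequences are worth knowing. First, with purely additive
noise the criterion is minimised by very large λ, i.e. a near-linear
transform — the correct answer. Second, once the data sit in the
logarithmic regime the criterion is nearly flat in λ, so the selected λ
can wander within that regime; this changes each feature's values only by
an approximately constant offset, which the downstream intercept absorbs.
The one place where such per-feature offsets would matter — the
reagent-concordance filter, which correlates values across features — is
therefore computed on per-feature standardised values. The transform is
fitted globally per feature, not per batch.

## Quality control

Two hard filters with strict inequalities:

* **Feature reproducibility** (`featureReproducibility()`): Pearson
  correlation of each feature between two replicate measurements across
  experiments; features must exceed 0.6. A feature at exactly the
  threshold fails. Fewer than three complete pairs gives the label
  `"insufficient"` instead of a pass/fail verdict.
* **Reagent concordance** (`reagentConcordance()`): for each target gene,
  the Pearson correlation between the flattened phenotypic profiles of its
  two dsRNA designs over all query reagents and features must exceed 0.7.
  Genes failing this are treated as having at least one off-target or
  inefficient reagent and are removed (`filterScreen()`, idempotent, never
  altering retained values). Profiles are standardised per feature
  (screen-wide mean/SD) before flattening so every feature contributes
  comparably; pairwise-complete entries are used, and genes with under
  half of their profile observed are `"insufficient"`.

## Non-redundant feature selection

Many image features are near-duplicates. `selectFeatures()` starts from
three interpretable seed phenotypes — cell number, mitotic index, cell
area — and grows the set greedily. For every candidate it fits, within
each replicate separately, a linear regression of the candidate on the
already-selected features; the *gain* is the Pearson correlation of the
two replicates' residual vectors — reproducible information not yet
covered. Fitting per replicate keeps the gain an honest reproducibility
measure: correlated noise cannot masquerade as signal. At each step the
fraction of candidates with positive gain is computed first; the iteration
stops as soon as it no longer exceeds 0.5, because for uninformative
candidates positive and negative residual correlations are equally likely.
Ties on the maximal gain break to the lexicographically smaller name,
making the procedure invariant to input column order. Candidates that
failed the 0.6 reproducibility screen never enter. One behaviour to
expect: a noisy copy of a selected feature retains a small positive gain
(regression on a noisy regressor cannot remove the shared factor
entirely), so late steps may admit weakly redundant features before the
stop fires; the planted-factor features are always found first.

`selectQueryPanel()` addresses the complementary design question — which
query genes to spend columns on — by greedy forward selection maximising
the fraction of total matrix variance explained when every other column is
regressed on the selected ones (selected columns count as explained, which
makes the curve monotone and reach 1 at the full panel).

## π-scores and moderated tests

`fitMainEffects()` estimates the additive decomposition per feature and
per (target design, query design) combination by **two-way median
polish** — robust, so the interacting minority of pairs does not
contaminate the main effects; the invariants tests plant 10% contaminated
cells and require main effects unchanged to $10^{-6}$. Polish runs to a
$10^{-9}$ tolerance (at most 100 iterations) followed by explicit final
centring sweeps, so the returned π-tensor has row and column medians below
$10^{-8}$ and effect vectors have exact zero medians over genes (the
shifts go into the intercept). Main effects come from the double-knockdown
matrix itself — every target faces all queries, which makes the polish
well-posed — rather than from separate single-knockdown wells; single
wells, when present, serve the QC and feature-selection stages. Matrices
smaller than 10 × 10 are refused (medians are too unstable); genes with
more than half of a polish matrix row/column missing are flagged.

`summarizeInteractions()` tests, per gene pair and feature, the mean of
the four reagent-pair π values against zero with an empirical-Bayes
moderated t-test: sample variances (3 degrees of freedom at full
occupancy) are shrunk towards a prior variance $s_0^2$ with prior degrees
of freedom $d_0$ estimated per feature by scaled-F moment matching on the
log sample variances across all gene pairs, giving
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ and
$t = \bar\pi / (\tilde s / \sqrt n)$ on $d_0 + d$ degrees of freedom. With
so few replicates, the shrinkage is what keeps the test calibrated; the
$d_0 \to \infty$ limit reduces to the closed form $\bar\pi/(s_0/\sqrt n)$
and is verified to $10^{-8}$ in the tests. Benjamini–Hochberg adjustment
is applied within each feature across all gene pairs (per-feature calls
are the unit of reporting; the "significant in ≥ 1 feature" criterion is
applied afterwards); pairs with fewer than two π values are not tested.
Null simulations (10⁴ pairs × 4 values) keep the fraction of adjusted
p < 0.01 below 0.012.

One caveat the synthetic benchmarks make visible: median-polish residuals
of non-interacting pairs inherit small row/column estimation errors that
are correlated across the four reagent pairs, so at small screen sizes
(12 queries) the realised false-discovery proportion among detected pairs
can exceed the nominal feature-level FDR. With the 72-query geometry of a
production screen the effect shrinks with the median's estimation error.

## Directional calls

`fitDirectionModels()` averages the up to four reagent-pair π vectors into
one gene-level vector per pair and averages the two designs' effect
vectors (stacking the reagent-level observations with design-matched
covariates is available via `aggregate = "stack"`; averaging was chosen as
the default because the four measurements estimate the same gene-level
relation and averaging quarters the noise share of the π sum of squares,
which the fraction thresholds act on). The least-squares fit
$\pi = \alpha a + \beta b$ uses no intercept. Explained fractions are
type-II — the extra sum of squares of each covariate given the other,
divided by the total sum of squares of π, clamped to $[0,1]$ — making them
order-invariant and, for orthogonal effect vectors, exactly additive with
the residual fraction. Pairs whose effect vectors are nearly collinear
(|cos angle| > 0.99) are unidentifiable: if two genes produce the same
phenotype direction, no geometry can say who acts on whom.

Fits are computed for **all** gene pairs; `deriveThresholds()` takes the
10% and 95% quantiles (linear interpolation) of the pooled
{frac$_A$, frac$_B$} values over the whole screen, and `callDirections()`
emits A → B only for pairs with a significant interaction (FDR 0.01) where
frac$_A < \theta_{low}$ and frac$_B > \theta_{high}$. Pooling both sides
into one distribution, rather than per side, follows from the sides being
exchangeable. At most one call per pair is possible since
$\theta_{low} < \theta_{high}$. This rule is deliberately conservative:
$\theta_{low}$ sits in the extreme left tail of the screen-wide fraction
distribution, so only pairs with a strikingly one-sided geometry are
called. On synthetic benchmarks the calls that are made are essentially
always correct in direction and sign, while the majority of genuinely
directional pairs remain uncalled — precision is bought with recall, which
matches the intended use: nominating high-confidence regulatory
directions, not cataloguing all of them.

## Profile-correlation network

`buildProfileMatrix()` lays each target gene's interaction profile — mean
π over reagent pairs, across all queries and features — into a row;
self-pair columns are blanked. `buildCorrelationGraph()` connects genes
whose profiles correlate at Pearson r ≥ 0.6 (inclusive, on
pairwise-complete columns; pairs sharing fewer than 3 columns are left
unconnected). Profiles are effect-size quantities (π means, not
t-statistics) and are correlated jointly across features without
per-feature standardisation — π values are already residuals on a common
transformed scale. Genes in the same complex or pathway share interaction
partners and phenotypes, so connected components at this threshold recover
planted complexes in the synthetic screens with Rand index ≥ 0.95.

# The synthetic screen generator

`simulateScreen()` is a first-class module, not a test fixture: it is the
package's substitute for re-running a multi-month imaging campaign. On the
transformed scale it draws $y = m + a + b + \pi + \varepsilon$ and emits
raw values through the exact inverse transform, plus single-knockdown
replicate tables and the complete ground truth. The default study
conditions are:

| condition | default | rationale |
|---|---|---|
| screen size | 50 targets × 12 queries × 2 × 2 designs | smallest geometry at which polish, quantiles and BH are all well-behaved, and a full pipeline run stays in seconds |
| features | 20, first three named as the seeds | matches a selected non-redundant phenotype panel |
| main-effect SD | 1 (transformed scale) | sets the unit |
| interacting pairs | 10% | of the order observed in cell-based double-knockdown screens |
| directional share | 50% of interacting pairs, coefficient \|c\| = 0.8, signs half alleviating | strong but not saturated directional geometry |
| symmetric π | isotropic, per-feature SD 0.8 | comparable in magnitude to directional interactions |
| noise SD | 0.25 (25% of effect SD) | realistic well-to-well reproducibility after transformation |
| discordant designs | 6% of targets; additive shifts (SD 3) on half the features of design 2 | emulates off-target reagents with the low-concordance signature the QC filter targets |

A planted A → B pair satisfies π = c · (B's effect vector) exactly before
noise; symmetric pairs draw isotropic π; optional `nComplexes` groups of
targets share one interaction profile for network studies. Everything is
reproducible bit-for-bit from the seed.

What the generator deliberately does **not** emulate: plate-position and
edge effects, batch drift, correlated feature noise (features are
independent given the effects), image segmentation artefacts, and
dose-dependent reagent efficiency. Passing the synthetic benchmarks
therefore demonstrates the correctness and calibration of the statistical
machinery under the stated model, not robustness to every failure mode of
real imaging data — the QC filters exist precisely because real screens
violate the clean model in ways the generator only sketches (the
discordant-reagent mechanism).

# Numerical choices and degenerate inputs

* Median polish: tolerance $10^{-9}$ on the residual change, ≤ 100
  iterations, then explicit median-centring sweeps to below $10^{-12}$
  per sweep step; `NA`-aware throughout.
* Prior fit: scaled-F moment matching; all-zero variances fall back to
  the $d_0 = \infty$ branch with a warning; a failed fit falls back to
  $d_0 = \infty$ with the pooled variance.
* Zero π quadruplets give t = 0, p = 1 (not NaN); pairs with n < 2 are
  reported untested.
* Quantile thresholds use type-7 (linear interpolation) quantiles; a
  degenerate fraction distribution (all equal) or fewer than 20 fitted
  pairs is an error rather than a silent threshold.
* Ties in feature selection and query-panel selection break
  lexicographically; both procedures are deterministic given the data.
* Transform: non-finite inputs become `NA` and are carried, never
  dropped; inverse-transform overflow raises an error.
* Benchmark problem sizes used in the tests and the acceptance script —
  50 × 12 × 20 screens, 10⁴-pair null simulations, 1000-experiment
  replicate tables — were chosen so every stage's statistical behaviour
  (quantiles, BH, polish robustness) is exercised at well-posed sizes
  while a complete run remains a desk-scale computation.

# Known limitations

* Direction calls need phenotypic diversity: with few features, or
  correlated features, effect vectors collinearity rises and with it the
  unidentifiable fraction.
* The quantile-based caller is conservative by construction (see above);
  its recall depends on the screen-wide fraction distribution, so adding
  screens together changes the thresholds.
* Mixed epistasis — different directions on different phenotype
  subsets — is not modelled; one coefficient pair per gene pair.
* BH within feature treats features as separate families; a global
  adjustment over the feature × pair grid is stricter and can be obtained
  by adjusting the exported p-values externally.
* Main effects estimated by polish are relative (median-centred); the
  single-gene phenotype test therefore needs an explicit null reference
  (control wells or null centres).

# A complete run

```{r pipeline, eval = FALSE}
res <- runPipeline(list(seed = 1L), outDir = "episcan_run")
res$thresholds
head(res$calls)
```

Every artefact (transformation parameters, QC report, selection trace,
interaction statistics, directed calls, network) is also written as
TSV/GraphML, and `inst/scripts/episcan.R` exposes the same stages as shell
subcommands.
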