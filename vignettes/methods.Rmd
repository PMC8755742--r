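---
title: "Models and design of the afproteo pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the afproteo pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afproteo)
```

`afproteo` analyzes gestational-age modulation of the amniotic fluid
proteome measured on aptamer panels. This vignette explains the models
behind each stage, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
and design choices a maintainer should know about. Nothing here claims
an empirical result that the test suite or `scripts/acceptance.R` does
not itself compute.

## Normalization model

Aptamer panels report relative fluorescence units (RFU) whose scale
varies by sample, dilution bin, and plate. The vendor's standardization
is described only qualitatively in the literature, so the package
implements a transparent median-ratio emulation, each step optional:

* **Hybridization normalization.** Per sample `s`, the factor is the
  median over spiked control reagents of `reference / observed`; the
  whole sample row is multiplied by it. Afterwards, each sample's median
  control ratio is exactly 1. Controls are spiked oligonucleotide
  references, so treating their reference levels as known is faithful to
  the assay.
* **Median normalization.** Per sample and dilution bin, the factor is
  the median over bin analytes of (across-sample analyte median /
  analyte value in this sample). Whether the real procedure works within
  bins or globally is not documented; within-bin is the default and a
  `global` flag provides the fallback.
* **Plate calibration.** Per plate and analyte, the factor is
  `reference / median over the plate's calibrator samples`. When no
  calibrator samples are designated, all plate samples calibrate; when
  no reference is given, the all-sample median per analyte is used. A
  plates-by-analytes reference matrix is also accepted, mirroring the
  situation where calibrator runs provide expected per-plate levels.

Factor direction is always `reference / observed`, i.e. factors multiply
observations toward the reference.

A caution established while testing: all three steps are scale
corrections on the log2 scale, but only *exact* inversion of planted
factors leaves group contrasts untouched. A data-driven plate reference
on plates whose group composition differs (here, random plate
assignment of 15 + 13 samples) moves group contrasts, because the plate
medians absorb part of the group effect. The test suite demonstrates
both regimes: exact contrast preservation to 1e-9 with
calibrator-derived per-plate references, and approximate preservation
(correlation > 0.999) for the fully data-driven chain including the
median step.

## Differential abundance

Each analyte is fit by ordinary least squares on the log2 scale:

    log2(abundance) ~ group + fetal sex + maternal age

Covariates default to the two variables that differ between
gestational-age groups in this design; maternal age enters as a
continuous covariate, and the covariate list is a parameter (the
late-vs-early contrast uses the same list by default). The group
coefficient is the log2 fold change. Residual variances `s²` (common
residual df `d`) are moderated by the empirical-Bayes model in which
true variances follow a scaled inverse chi-square prior with
hyperparameters `(d₀, s₀²)`: the posterior variance is
`s̃² = (d₀ s₀² + d s²)/(d₀ + d)` and the moderated
`t = β̂ / (v^{1/2} s̃)` has `d₀ + d` degrees of freedom.
Hyperparameters are fitted by method of moments on `log s²` using
digamma/trigamma matching, with a Newton inversion of the trigamma
function. Two limits anchor the implementation: `d₀ = 0` reduces every
statistic to the ordinary OLS t-test (asserted to 1e-10), and
homogeneous variances drive `d₀ → ∞`, where `s₀²` becomes the pooled
arithmetic mean of the `s²` (the common-variance MLE). The finite-`d₀`
path agrees with the reference Bioconductor implementation to 1e-8 in
the test suite.

Calls require `q < 0.1` (strict, Benjamini–Hochberg) *and* fold change
`≥ 1.5` (inclusive); fold change is reported unsigned with a separate
direction column. The early/late midtrimester split is at 21.05 weeks,
implementing disjoint printed ranges (21.0 weeks is early, 21.1 late)
with no ties possible at one-decimal gestational-age precision.

## PCA

Columns are centered and unit-scaled by default before singular value
decomposition (scaling is exposed as a flag because analytes span very
different dynamic ranges); zero-variance analytes are dropped and
recorded. Component signs follow the largest-loading-positive rule, and
the PC1–gestational-age correlation is reported both signed and as
`|r|`, since component orientation is a convention.

## Network modules

The module stage runs on the union of differentially abundant analytes
from both contrasts. Edges derive from the biweight midcorrelation
(median/MAD-based, tuning constant 9; analytes with zero MAD fall back
to mean-centering so their correlations reduce to Pearson, with a
warning), a signed adjacency `a = ((1 + ρ)/2)^β` with `β = 22`, and the
topological overlap measure
`TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)`.

Module detection is a static average-linkage tree cut with three
deliberate design choices, made after the straightforward defaults
failed their recovery benchmarks:

1. **Cut height.** A fixed high quantile of the merge heights collapses
   modules that share an effect direction (their members correlate
   through the common group contrast). Instead, candidate heights (the
   50th–99.5th merge-height percentiles, capped at an absolute TOM
   dissimilarity of 0.995) are scanned for the cut producing the most
   clusters of at least `min_module_size` (default 20), ties broken
   toward the cut assigning the most analytes. The 0.995 cap encodes
   that clusters cohering only at near-maximal dissimilarity — the
   regime of a structureless network at high soft-threshold power — are
   not admissible modules; a pure-noise matrix therefore yields only the
   background module.
2. **Eigenprofile merging.** Modules whose eigenprofiles correlate above
   `merge_corr = 0.85` merge iteratively (the complement of the common
   0.15 merge cut).
3. **kME rescue.** Background analytes whose correlation with a module
   eigenprofile reaches 0.5 are assigned to the best-matching module.
   This is the analogue of the partitioning stage of hybrid tree
   cutting: without it, average linkage sheds peripheral members of
   tight modules into the background, and recovery of planted
   three-module structure drops from an adjusted Rand index of ~0.93 to
   ~0.5. Under the null this rescue is inert — a noise analyte's kME
   has standard deviation `≈ 1/√(n−1) ≈ 0.19` at n = 28, so 0.5 is a
   2.6-sigma bar — and the pure-noise behavior above is unchanged.

Eigenprofiles are the first principal component of the standardized
member profiles, unit-norm and oriented so the mean member correlation
is nonnegative; kME is each analyte's Pearson correlation with an
eigenprofile, and hubs are the top four members by kME (ties broken by
analyte id). Gestational-age trajectories of eigenprofiles and hubs use
LOESS (local quadratic, tricube weights, span 0.75, direct surface
evaluation) on an even grid over the observed range.

## Enrichment, tissue signatures, concordance

Over-representation uses the upper hypergeometric tail `P(X ≥ k)` for
each flat gene set against the panel-gene universe, keeping terms with
at least 3 query hits before BH adjustment (q < 0.05). The test is
unconditional and database-free: term relationships are deliberately
not modeled, and sets are supplied as GMT files.

Tissue signatures operationalize "expressed ≥ 30 times higher in one
tissue" as a ratio against the *median* of the other tissues (the
maximum is available by flag), capped at the top 20 panel-measured
genes per tissue by descending ratio with deterministic id tie-breaks.
Signature analytes are Z-scored against the midtrimester reference
(mean 0, SD 1 in the reference by construction), averaged per sample
and tissue, and compared between groups by Wilcoxon rank-sum — exact
two-sided p for group sizes ≤ 25 without ties, normal approximation
with tie correction otherwise — with BH across tissues (q < 0.05).
Multi-gene reagents count once per tissue if any mapped symbol is a
member.

Concordance with an external differential table matches upper-cased
gene symbols (multi-gene reagents match on any symbol; multiplicities
are flagged), restricts to molecules significant in both studies,
and reports Spearman's rho plus the same-direction fraction, with a
zero fold change counted as disagreement.

## The synthetic cohort generator

`simulate_cohort()` emulates the target study design: 15 midtrimester
samples with gestational age uniform on [16.4, 24.0] weeks and 13 term
samples on [37.0, 41.0]; 1310 analytes of which 10 are noise-free
spiked controls; 25% of the panel carries a true group effect with
`|log2FC| = log2(1.5) + Exponential(1)` so every planted effect clears
the calling threshold; per-analyte noise variances follow the scaled
inverse chi-square prior with `(d₀, s₀²) = (4, 0.25)`; per-analyte
fetal-sex, maternal-age, and (weak) BMI coefficients are Gaussian with
SDs 0.2, 0.02, and 0.005; per-sample hybridization factors and
per-plate-by-analyte calibration factors are log-normal (sdlog 0.2 and
0.1, two plates); dilution bins follow baseline-abundance tertiles.

Three protein modules (sizes 110/100/90) are planted *among the
affected analytes*, matching the design in which networks are built on
the differentially abundant set. Each module has a latent
gestational-age trajectory — U-shaped, decreasing, or increasing,
mutually near-orthogonal within groups — with member loadings uniform
on [0.4, 0.9], and member effect signs coherent with the trajectory
(decreasing modules are down at term). Factors are centered within each
group so module membership adds correlation structure without a
group-mean effect. The factor amplitude defaults to 0.5 log2 units,
about half the median analyte noise SD: co-regulation is present but
subordinate to intrinsic noise, which is the regime in which the
differential-calling error rates quoted below are achieved. The module
*recovery* benchmark instead uses amplitude 1.5, the strong
co-regulation regime in which module structure dominates and recovery
is a well-posed target; both regimes are exercised in the tests.

Five tissues receive 10 signature genes each, drawn from unaffected
single-gene analytes; the atlas gives signature genes 40–80 times the
median of the other tissues, and the first tissue's analytes receive a
term-group shift of one noise-SD, recorded in the ground truth.
Prior-study tables are correlation-controlled mixtures
`prior = c·t + √(1−c²)·sd(t)·z`, left uncentered so `c = 1` reproduces
the truth exactly, with Bernoulli significance flags.

What the generator does **not** emulate: limit-of-detection censoring,
aptamer cross-reactivity, sample contamination, non-Gaussian noise,
missing values, or real gene identities and set structure. Passing
recovery tests therefore demonstrates the correctness and calibration
of the algorithms under the stated generative model, not performance on
real assay data.

## Benchmarks the package holds itself to

Computed by the test suite (and, in reduced form, by
`scripts/acceptance.R`) on generator data:

* Six demographic Fisher p-values from published 2×2 counts reproduced
  at three decimals, with `stats::fisher.test` as an independent route.
* Closed-form statistics equal brute-force oracles: hypergeometric
  tails vs complete enumeration (N ≤ 15), moderated t at `d₀ = 0` vs
  OLS (1e-10), exact Wilcoxon vs rank-assignment enumeration
  (n₁ + n₂ ≤ 10), LOESS on noiseless linear data (1e-6).
* Differential calling on 100 simulated cohorts: empirical FDR at
  q < 0.1 stays below 0.15 (observed ≈ 0.06) and sensitivity for
  planted `|log2FC| ≥ 1` stays above 0.9.
* Hyperparameters `(4, 0.25)` recovered within 15% over 20 replicates
  of 2000 analytes (observed within ~1%).
* Planted three-module structure recovered with mean adjusted Rand
  ≥ 0.8 over 20 seeds in the strong co-regulation regime (observed
  ≈ 0.93).
* Planted hybridization and plate factors inverted to 1e-6 relative
  error; planted tissue signatures recovered exactly and the planted
  shift called at q < 0.05 with unshifted tissues near the nominal
  rate; constructed concordance at mixture correlation 0.6 recovered
  within ±0.1 of its Monte-Carlo expectation over 50 seeds.

Problem sizes in the routine test run are scaled to the study's own
dimensions (28 samples, 1310 analytes; smaller 220-analyte cohorts for
unit tests), keeping the full suite around half a minute.

## Known limitations

* The module detector is a deliberate simplification of hybrid dynamic
  tree cutting; its adequacy is defined by the recovery benchmarks, and
  very unbalanced or weakly separated module structures may still be
  merged or shed to the background.
* Median normalization is data-driven and perturbs group contrasts at
  order `noise/√(bin size)`; with group-imbalanced plates the same is
  true of plate calibration unless calibrator references are supplied.
* The empirical-Bayes model assumes a common residual df across
  analytes (one shared design, no missing values), which the ingest
  layer enforces by rejecting incomplete matrices.
* Enrichment treats gene sets as flat and independent; no ontology
  graph propagation or conditional testing is attempted.
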