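---
title: "Methods: twin-cohort immunoglobulin glycomics with glycotwin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin-cohort immunoglobulin glycomics with glycotwin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycotwin)
```

`glycotwin` implements the statistical machinery of a twin-cohort
immunoglobulin glycomics study: compositional preprocessing of
glycopeptide panels, twin variance decomposition and shared heritability,
enzymatic conversion-rate ratios, and a kinship-aware GWAS. This vignette
explains each model, its assumptions, the tunable parameters, and the
numerical and design choices made where the methodology left them open.

## Glycopeptide preprocessing

Raw LC-MS intensities arrive as an individuals × glycoforms matrix whose
columns are named `<PEPTIDE>_HhNnFfSs` — the tryptic peptide code followed
by the glycan composition (hexoses H, N-acetylhexosamines N, fucoses F,
sialic acids S). Absolute intensities are not comparable across runs, so
the pipeline is compositional and runs in a fixed, logged order:

1. **Total-area normalisation** (`total_area_normalize()`): each intensity
   is divided by the intensity sum of all glycoforms sharing its peptide,
   per individual. Within each individual the non-missing abundances of a
   peptide then sum to 1 (closure, enforced to 1e-9). A peptide whose
   intensities are all zero for an individual becomes missing rather than
   0/0, since a zero total carries no compositional information.
2. **Outlier masking** (`remove_outliers()`, `k = 4` SD): a single pass —
   the mean and SD are computed once from all non-missing values, and
   entries *strictly* more than `k` SDs from the mean are masked. A value
   exactly at the fence is retained; a constant vector (SD 0) masks
   nothing. The single-pass reading keeps the rule idempotent on the
   retained data and matches the usual order "removal, then
   normalisation".
3. **Quantile normalisation** (`quantile_normalize()`): rank-based
   inverse-normal transform, rank `r` among `n` non-missing values (ties
   averaged) mapped to `qnorm(r / (n + 1))`. The transform only claims to
   make the marginal distribution normal; the `r/(n+1)` offset is the
   default and Blom's `(r − 3/8)/(n + 1/4)` is available — for the panel
   sizes involved the two differ by far less than any downstream
   tolerance.

Conversion-rate ratios are computed on the *untransformed* relative
abundances after outlier masking (stage `"outlier-filtered"`); association
and twin models consume the quantile-normalised stage.

**Derived traits** (`compute_derived_traits()`) are weighted-sum ratios
over one peptide's glycoforms,
`sum(w_num * abundance) / sum(w_den * abundance)` (denominator `"1"` for a
plain weighted sum). Definitions are config-driven (YAML;
`read_trait_definitions()`; an example ships in
`inst/extdata/derived_traits_example.yaml`) because the exact trait
catalogue is study-specific; `standard_trait_definitions()` generates the
usual families (sialylation, galactosylation, fucosylation, bisection) for
any parsed panel. Zero denominators yield missing values with a logged
count rather than errors — compositional zeros are expected at small
abundance. How sub-detection-limit glycoforms were treated upstream is not
specified by the methodology this package follows; the pipeline simply
propagates missing values.

## The synthetic twin cohort

Every stage is exercised on generated data with known ground truth. The
generator's defaults describe a large adult volunteer twin registry: 513
MZ pairs, 615 DZ pairs and 167 singletons, 78% female, ages uniform on
19–88 years, and round-robin plate assignment by family (so plate is not
confounded with zygosity).

* **Genotypes** (`simulate_genotypes()`): a parental-gamete model. Each
  family gets two parents with independent alleles at a frequency drawn
  uniformly from `maf_range` per SNP; children inherit one gamete per
  parent with free recombination. MZ co-twins share one genome (dosage
  rows identical by construction), DZ co-twins draw independent gametes
  (expected dosage correlation 1/2). Realised minor-allele frequencies are
  recomputed from the dosages. No linkage disequilibrium is simulated
  beyond family structure; `simulate_ld_block()` provides a separate
  haplotype-copy construction (per-allele flip probability) for
  conditional-scan studies.
* **Traits** (`simulate_twin_traits()`): latent trait = explicit SNP
  effects on standardised dosages + polygenic A + shared C + unique E +
  age/sex/plate effects. The polygenic component is drawn directly as a
  Gaussian pair component with cross-twin correlation 1 (MZ) / 0.5 (DZ)
  rather than as many small-effect SNPs — the twin models only see
  covariances, and the direct draw gives exact correlation control. The
  residual polygenic variance is `a2 − sum(beta²)`, so the total additive
  variance equals the configured `a2`. Dosages are standardised by
  `sqrt(2pq)` when effects are applied, putting `beta` on the
  per-standardised-allele scale and making each SNP's variance
  contribution exactly `beta²` (equivalently `2pq` times the squared
  per-allele effect).
* **Trait pairs** (`simulate_bivariate_traits()`): residual polygenic,
  shared-environment and unique-environment channels are cross-correlated
  (`rho_g`, `rho_c`, `rho_e`); a SNP shared by both trait models
  additionally contributes `beta_x * beta_y` of genetic covariance, which
  is what the conditional-covariance analysis removes.
* **Glycoform panels** (`simulate_glycoform_panel()`): per peptide, the
  allocation is logistic-normal — a softmax of Gaussian scores, strictly
  positive and summing to 1, monotone in the latent trait, with the
  latent loading equal to the glycoform's count of the chosen feature
  residue. When a target mean feature fraction is requested, a common
  shift of the feature-carrying forms is calibrated by root-finding on the
  realised scores, so the softmax nonlinearity is accounted for. The
  generator records its own per-individual allocation-derived traits, and
  recomputing them from the emitted abundances reproduces them exactly —
  the recovery tests check the bookkeeping, not a distributional
  approximation.

What the generator does **not** emulate: mass-spectral noise and
peak-assignment error, missingness mechanisms tied to detection limits,
LD beyond single blocks, assortative mating, and subclass mixing at
peptide clusters shared between Ig subclasses (each panel is one
compositional unit). Passing tests therefore demonstrate correctness of
the estimators under the stated generative model, not robustness to those
real-data features.

## Univariate twin model

`twin_ace()` fits the classical twin model by maximum likelihood: each
pair is bivariate normal with common mean `mu` and variance, and expected
within-pair covariance `a² + c²` (MZ) or `a²/2 + c²` (DZ). Assumptions are
the standard ones: equal environments across zygosities, no dominance or
epistasis in A, no gene–environment interaction, and random mating.
Covariate adjustment is two-stage — residualise (age, sex as fixed
effects; plate and family as random intercepts where requested), then
standardise and fit — keeping the pair likelihood 2-variate.

Numerical choices:

* Components are parameterised as squared path coefficients
  `(pa, pc, pe)`, so estimates are bounded to `[0, 1]` after normalisation
  and the `c² = 0` boundary is reachable (at `pc = 0`). Optimisation is
  Nelder-Mead on sufficient statistics (per-zygosity sums, squares and
  cross-products), restarted once from its own optimum (`reltol` 1e-12),
  which makes a fit on thousands of pairs essentially instantaneous.
* Standard errors come from the observed information at the optimum,
  delta-method-transformed to the `(a², c², e²)` scale. At a boundary the
  information matrix can be singular; SEs are then reported as `NA` rather
  than fabricated.
* Starting values are Falconer's method-of-moments estimates clipped to
  the interior.
* `twin_ace_select()` fits ACE, AE, CE and E and picks the smallest
  `AIC = 2k − 2 logL` (k = free parameters including the mean); exact ties
  break toward fewer parameters; non-convergent fits are excluded with a
  warning.
* Twin order within a pair is as given; the pair likelihood is symmetric
  under swapping co-twins, and the tests verify the estimates are too.

## Bivariate twin model and shared heritability

`twin_bivar()` fits the bivariate AE model: each pair contributes a
4-variate normal observation with within-individual covariance `G + E`
and cross-twin block `r G` (`r` = 1 MZ, 0.5 DZ), where the 2×2 genetic
and environmental covariances are Cholesky-parameterised, guaranteeing
positive semi-definiteness without constraints. AE (not ACE) is the
default because the downstream shared-heritability arithmetic uses only
`h²` and `1 − h²`; a shared-C channel is available in the generator to
probe the misspecification. Likelihood-ratio tests for `ρG = 0`,
`ρE = 0` and `ρP = 0` refit with the corresponding covariance constrained
to zero (`ρP = 0` via the substitution `E12 = −G12`) and use the naive
χ²(1) reference — standard practice, exact for interior correlation
values, and only approximate near the ±1 boundary where the Cholesky
parameterisation approaches singularity from inside (a trait paired with
a copy of itself estimates correlations slightly below 1 for this
reason).

`shared_heritability()` then evaluates, exactly,
`COV_G = ρG √h²x √h²y`, `COV_E = ρE √(1−h²x) √(1−h²y)` and
`h²xy = COV_G / (COV_G + COV_E)`, constraining a correlation to zero when
its p-value exceeds 0.05 (so its covariance contribution vanishes). When
`COV_G + COV_E = 0` the ratio is undefined and flagged; when the two
covariances have opposite signs `h²xy` falls outside `[0, 1]` and is
flagged rather than truncated. `conditional_genetic_covariance()`
residualises both traits on covariates plus lead-SNP dosages, refits, and
reports `Ax · Ay · ρG` with the proportion of the unconditional genetic
covariance removed.

## Association, effective tests and correlation networks

`fit_lmm()` wraps a REML linear mixed model (via lme4) with fixed
covariates and random intercepts — the standard age/sex association model
with plate and family absorbing batch and relatedness. Family enters as a
family-level random intercept; this descriptive model does not
distinguish MZ from DZ covariance (the twin models do). Wald tests on the
normal approximation are used for fixed effects: the hypotheses are
single-coefficient and the cohort sizes make the t/normal distinction
immaterial.

The Li–Ji effective number of independent tests maps each eigenvalue λ of
the trait correlation matrix to `I(|λ| ≥ 1) + (|λ| − floor(|λ|))` and
sums. Numerically integer eigenvalues are snapped (tolerance 1e-8) before
`floor()`, otherwise a perfectly correlated panel's eigenvalue 4 − 1e-16
would contribute ~1 instead of 0. The raw real value is reported alongside
the integer used for Bonferroni division (rounded by default, floor by
option). Correlation networks keep a trait pair as an edge only when
|ρ| exceeds 0.25 **and** p is below the applicable Bonferroni bound:
`α / (N(N−1)/2)` within a class and `α / (N_A N_B)` between classes, with
N the class' effective test count. Pearson p-values use the t
approximation on pairwise-complete observations.

## Enzymatic conversion ratios

Reaction pairs are same-peptide glycoforms differing by exactly +1 in one
residue type; chains are maximal directed paths of at least two steps.
Ratios are product/substrate on untransformed relative frequencies; a zero
or missing substrate yields a missing ratio, never an infinity.
Consecutive junctions are compared with the *paired* Wilcoxon signed-rank
test by default — both ratios come from the same individuals — with the
rank-sum variant available by flag. Ratios are never log-transformed
before testing; rank tests are invariant to monotone transforms. The
Bonferroni denominator is the number of junctions actually tested in the
current run, reported explicitly: published per-study junction counts do
not transfer across panels, and the printed worked division in the source
literature for this step is internally inconsistent (a threshold quoted as
0.05/31 equals the value of 0.05/21), which is exactly why the
implementation always computes `α/m` from its own count.

## Kinship-aware GWAS

`run_gwas()` is a two-step (P3D-style) mixed-model scan. The kinship
matrix is either the pedigree expectation (MZ 1, DZ 0.5, otherwise 0) or
the empirical GRM `XXᵀ/m` on standardised dosages. Variance components
are REML-estimated once under the covariates-only null by profiling the
ratio `δ = σe²/σg²` on the eigenbasis of K (the profile is optimised on
`log δ ∈ [−30, 15]`); each SNP is then tested by GLS with the rotation
and weights held fixed. Per-SNP residual variance is re-estimated from
the weighted fit, so with identity kinship and no covariates the scan
reduces *exactly* to per-SNP OLS (t-test, n − p df) — a tested
invariant. Rotated coordinates whose variance weight is numerically zero
(degenerate kinship eigenvalues, e.g. literal duplicate individuals)
are dropped and the residual degrees of freedom counted on the
informative subspace; without this, duplicated samples would halve the
residual variance estimate and inflate every test. Effect alleles are
oriented to the minor allele; SNPs at or below the MAF floor (default
0.05) are excluded and counted.

Remaining pieces: genomic inflation `λ = median(χ²)/0.4549`;
`conditional_scan()` iteratively adds the current lead SNP's dosage to
the covariates and rescans the window until nothing passes the
genome-wide threshold (SNPs collinear with a lead are reported as missing
rather than crashing the scan); `σ = 2pqβ²` per SNP with totals over
independent leads, and the share of *genetic* variance computed as
`σ_total / h²` with the twin-model heritability as denominator — the
methodology this follows does not state its denominator, and the twin
`h²` is the natural in-cohort choice; replication requires direction
concordance plus `p < α/m` with a strict inequality. Plate enters the
GWAS as a fixed covariate (the natural reading of "included as a
covariate"); genotype principal components are supported as covariates
but default off for the single-ancestry synthetic cohort. Tag-SNP
substitution in replication is exact-ID matching plus an optional
user-supplied tag map, since no LD reference panel is bundled.

## Problem sizes and runtime

The test and acceptance suites run at sizes chosen to keep Monte-Carlo
error well inside the asserted tolerances while remaining desk-scale:
univariate recovery at 2000 + 2000 pairs (±0.05 on components), AIC
selection over 50 seeds at 1000 + 1000 pairs, bivariate recovery at
2000 + 2000 pairs (±0.1 on ρG) with 200 null replicates of 300 + 300
pairs for LRT calibration, GWAS calibration at 1000 individuals × 5000
SNPs, and conditional scans at 1500 individuals. Sufficient-statistic
likelihoods make the twin fits O(1) in pair count after one pass over the
data, so the whole suite completes in a few minutes on one CPU.

## Known limitations

* The bivariate model is AE-only; a shared-environment channel in the fit
  (bivariate ACE) is not implemented, only simulated.
* LRT p-values near correlation boundaries inherit the usual χ²(1)
  approximation error.
* No dominance (ADE) or sex-limitation twin models; singletons contribute
  to covariate adjustment only.
* The GWAS is single-trait, additive, common-variant; no imputation,
  meta-analysis, LD-score methods or colocalization.
* Pedigree kinship covers twin pairs and singletons only — no extended
  pedigrees.
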