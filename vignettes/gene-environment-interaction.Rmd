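---
title: "Transcriptome-informed gene-based GxE interaction testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome-informed gene-based GxE interaction testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`gxescan` tests whether the effect of an environmental exposure on a binary
disease outcome is modified by gene-centric genetic variation, using
genetically predicted gene expression as prior functional information. The
pipeline has two stages.

**Stage 1 — expression weight training.** On a reference panel with both
genotypes and expression (a few hundred samples, e.g. a tissue-specific
RNA-seq panel), each gene's cis region (gene boundaries ± 500 kb by
default) is screened for a significant heritable expression component by
REML on a genetic relationship matrix (GRM); genes whose SNP-heritability
likelihood-ratio test has p ≥ 0.01 are discarded. For the remaining genes,
three weight models are trained — the single best marginal eQTL (`top1`),
LASSO and elastic net (mixing 0.5) — and the model with the best 5-fold
cross-validated R² becomes the gene's weight vector `w`.

**Stage 2 — mixed-effects interaction score test.** In a case-control
cohort, the gene-level interaction with an exposure `E` is decomposed into

* a **fixed-effect component**: a 1-df score test of the coefficient of
  `T·E`, where `T = Gw` is the predicted expression (a weighted burden of
  the gene's dosages), and
* a **random-effects component**: a variance-component score test of
  residual per-SNP interaction effects `b_j ~ N(0, τ²)` on the columns of
  `Z = diag(E) G`, with a mixture-of-chi-squares null.

Both are score tests against the logistic null model
`logit P(Y=1) = Xα + β_E E + β_T T`, where `X` holds the adjustment
covariates (intercept, study indicators, age, five genotype principal
components, and exposure-specific extras such as former menopausal hormone
therapy use). The two component p-values are combined by Fisher's method
(χ²₄) and by an adaptive weighted combination that scans a grid of weights
on the pair `(-ln p_fixed, -ln p_random)` and calibrates the minimum
analytic tail probability exactly.

A scan driver iterates genes × exposures, applies per-exposure eligibility
strata (all samples / parous women / pre- or postmenopausal women) and
complete-case filtering on the exposure, attaches per-exposure
Benjamini–Hochberg adjusted p-values, calls genome-wide significance at
`α / (n_genes × n_exposures)` and reports the genomic inflation factor
λ_GC with QQ coordinates per exposure.

# The component tests in detail

## Null model and fixed-effect score

The null logistic model is fitted by IRLS (`stats::glm.fit`, convergence
tolerance 1e-10). With fitted probabilities `μ`, working weights
`W = μ(1-μ)`, null design `D = [X, E, T]` and interaction column
`c = T∘E`, the fixed score is `U = c'(Y-μ)` with efficient variance
`V = c'Wc - c'WD (D'WD)⁻¹ D'Wc`; `U²/V` is referred to χ²₁. Fitted
probabilities within 1e-10 of 0 or 1 raise a separation error; constant or
aliased covariate columns are dropped (rank is assessed on unit-norm
columns so that covariate scale differences cannot masquerade as rank
deficiency), but a constant or aliased exposure or predicted-expression
column is an error, since the test would be meaningless.

## Independence construction for the random component

The random-effects score is `Q = ||Z'(Y-μ_a)||²`, where `μ_a` comes from
the null *augmented with the fixed interaction column* `c`. Projecting `c`
out of the random component makes the two component scores asymptotically
independent, which the combination methods require; it also means the
random component tests only interaction signal *not* expressible through
the predicted-expression burden. The null distribution of `Q` is
`Σ λ_k χ²₁`, with `λ_k` the eigenvalues of `Z'P_a Z` and
`P_a = W_a - W_a D_a (D_a'W_a D_a)⁻¹ D_a'W_a`. When the gene reduces to a
single SNP whose `Z` column is collinear with `c`, every eigenvalue
vanishes and the component reports a degenerate-test error rather than a
spurious p-value.

## Mixture tail probabilities

`mixture_tail_prob()` inverts the characteristic function of the
chi-square mixture (Imhof-form integrand) by adaptive quadrature.
Eigenvalues are first rescaled to mean 1 — the tail probability is
scale-invariant and the rescaling keeps the oscillatory integrand at a
characteristic scale near 1, where the quadrature is accurate. Inversion
is used down to p ≈ 1e-8; beyond that, or on quadrature failure, the
implementation switches to Liu–Tang–Zhang moment matching (noncentral
chi-square matched on three cumulants plus kurtosis) and flags the result
(`method = "liu"`). P-values are floored at 1e-300.

## Combining the components

Under the null, `u = -ln p_fixed` and `v = -ln p_random` are independent
Exp(1). Fisher's statistic `X = 2(u+v)` is χ²₄ with the closed-form
survival `e^{-X/2}(1 + X/2)`. The adaptive combination evaluates, for each
weight `λ` on a grid (default 0, 0.1, …, 1), the analytic tail of
`s(λ) = λu + (1-λ)v` — Exp(1) at the endpoints, Gamma(2, 2) at λ = 0.5,
and the two-rate hypoexponential closed form otherwise — and takes the
minimum. The reported p-value is the exact null probability that this
minimum falls below its observed value. That rejection region is a union
of half-planes in `(u, v)`; its probability under the product Exp(1)
measure reduces to a one-dimensional integral of a piecewise exponential
function over the lower envelope of the constraint lines, which is
evaluated in closed form segment by segment. No quadrature is involved, so
the calibration is exact to machine precision even for very small
p-values; a seeded Monte Carlo fallback (10⁶ pairs) exists for defensive
coverage and records itself in the output. The grid+min-p construction is
this package's own calibration of an adaptive weighted combination; it is
not claimed to replicate any specific published adaptive scheme.

# Synthetic data

The generator produces every ingredient the pipeline consumes, so the full
analysis runs and is tested without any external download.

* **Genotypes** (`simulate_ld_genotypes()`): two haplotypes per sample,
  each obtained by thresholding a block-autoregressive latent Gaussian
  (correlation `ρ^|i-j|` within a block, 0 between blocks) at the
  per-variant MAF quantile. This yields Hardy–Weinberg dosages with a
  controllable, reproducible LD profile. MAFs are drawn uniformly from a
  configurable range; the variant grid is fixed by the spec seed while
  haplotype draws take a separate seed, so a reference panel and a cohort
  population share loci but are independent samples.
* **Expression** (`simulate_expression_panel()`): `y = G_c β_c + ε` with
  the noise orthogonalized against the genetic value and both parts
  rescaled so the realized variance ratio equals the target heritability
  *exactly* on the panel — tests can therefore assert the generative h²
  without simulation slack. The default panel size follows the
  few-hundred-sample scale of tissue expression panels (251).
* **Cohort** (`simulate_cohort()`): disease outcomes follow
  `logit(p) = α₀ + Xγ + β_E E + β_T T + β_TE T·E + (Gb)·E` with
  `b_j ~ N(0, τ²)` drawn once per gene; cases and controls are then
  sampled without replacement to quota from a larger simulated population,
  mimicking outcome-dependent (ascertained) case-control sampling. The
  population should comfortably exceed the quotas; around 20× mimics a
  rare-disease ascertainment while balanced designs need only a modest
  multiple. Unreachable quotas raise an error suggesting an intercept
  adjustment. Emitted PCs are recomputed on the sampled cohort and are
  exactly orthonormal over its rows.
* **Exposures** (`make_exposures()`, `default_exposure_specs()`): fourteen
  risk-factor-style variables (reproductive history, alcohol, BMI by
  menopausal stratum, height, oral contraceptive use, smoking, MHT use)
  with the field's conventional analysis codings (per 5 years, per
  10 g/day, per 2 years, per 5 kg/m², per 12 months, per 5 cm), ordinal
  parity coded 1/2/3/4+ as an integer trend, and eligibility strata
  (parous-only, menopausal-status-specific) that blank the exposure
  outside its stratum. Means and prevalences approximate values typical of
  large European-ancestry breast cancer studies; no exact match to any
  particular cohort is claimed.

What the generator does *not* emulate: realistic human LD maps (block
AR(1) is a caricature), family or cryptic relatedness, imputation
uncertainty, platform batch structure beyond a `study` factor, and
confounding between exposures and ancestry. Passing calibration tests on
this generator therefore demonstrates correctness of the statistical
machinery under its stated assumptions, not robustness to every real-data
pathology.

# Numerical and design choices

* **REML.** The restricted likelihood of
  `y = Xc + g + e, g ~ N(0, σ²_g K)` is profiled over the heritability
  ratio on the spectral decomposition of the GRM, reducing each evaluation
  to weighted least squares in the rotated basis; a golden-section search
  over `h² ∈ [0, 1)` then finds the optimum exactly to tolerance. This
  one-dimensional profiling is preferred over AI-REML iterations for a
  single-GRM model: it cannot diverge, respects the `σ²_g ≥ 0` boundary by
  construction, and the decomposition can be shared across all genes
  trained on one panel (`grm_decompose()`), which makes the
  2,000-replicate gate-calibration runs cheap. The LRT against `σ²_g = 0`
  uses the boundary mixture `½χ²₀ + ½χ²₁`, i.e.
  `p = ½ P(χ²₁ ≥ LRT)` with `p = 0.5` at LRT = 0.
* **Weight schemes.** Elastic-net mixing is fixed at 0.5; the penalty path
  (100 values) and inner 5-fold CV come from `glmnet::cv.glmnet` with a
  seeded fold assignment. Weights are reported on the 0–2 dosage scale
  (glmnet standardizes internally and back-transforms). Ties in the
  5-fold CV selection break in the order enet > lasso > top1. Genes
  passing the heritability gate are kept even with non-positive CV R²; the
  gate is the only inclusion criterion.
* **Harmonization.** Weight variants are matched to cohort variants on
  chrom:pos; swapped ref/alt flips the dosage to `2 - d`;
  strand-complement matches are resolved after complementing; A/T and C/G
  variants are always dropped because their strand cannot be resolved —
  the standard practice that avoids silent sign errors. A gene is kept
  for testing if at least one nonzero-weight variant survives
  harmonization.
* **Multiple testing.** BH adjustment is applied per exposure over the
  genes tested for that exposure; the Bonferroni family is
  genes × exposures. Both are reported; the FDR < 0.2 "suggestive" call is
  a reporting flag, never a filter.
* **Eligibility and missingness.** Each exposure is analyzed complete-case
  within its eligibility stratum; missing exposures never propagate into
  other exposures' analyses. Strata smaller than 50 complete cases are
  skipped with a warning record.
* **Exposure codings.** Continuous exposures are divided by their coding
  scale before analysis. The interaction p-values are invariant to
  rescaling of the exposure (the scale is absorbed by the coefficients);
  a location shift is *not* an exact invariance of the random component,
  because shifting `E` adds per-SNP main-effect columns to `Z` that the
  null model deliberately omits — the burden `T` is the gene's only
  main-effect term, matching the hierarchical model.
* **Genotyping platforms.** Multi-platform cohorts are handled by the
  `study` covariate absorbing platform differences; no stratified or
  meta-analytic combination is attempted.

# Problem sizes used by the test suite

The suite validates calibration and power on desk-scale versions of the
design: 2,000 null case-control replicates of 1,000 cases + 1,000 controls
with a 50-SNP gene for type-I error and component independence; 200
replicates per effect size for the power ordering; 2,000 null genes
(n = 200 panel, 50 SNPs, shared GRM decomposition) for the heritability
gate; 50 replicates (n = 1,000 panel, 100 variants, 10 causal, h² = 0.5)
for held-out prediction accuracy; and 20 instances of n = 200 with 5 SNPs
against a 10,000-permutation oracle for the variance-component null.

On that last comparison: the analytic variance-component p-value is an
*unconditional* quantity (its randomness is the outcome vector under the
fitted null), whereas a permutation of the exposure within case/control
strata conditions on the observed exposure-genotype-weight coupling. At
n = 200 the two answers differ by a few hundredths in either direction on
individual instances even though both are correctly calibrated on average
(the analytic test's type-I error at this size is 0.048 at α = 0.05, and
it matches a parametric bootstrap of its own null within Monte-Carlo
error). Instance-level agreement within permutation Monte-Carlo error
should only be expected at larger sample sizes.

# Known limitations

* Expression models are single-tissue and cis-only; no cross-tissue
  borrowing or Bayesian sparse models.
* The adaptive combination's calibration assumes the two component
  p-values are exactly independent Exp(1) on the log scale; in finite
  samples the projection construction makes them only asymptotically so.
* The Liu fallback in the deep mixture tail is a moment approximation;
  results carrying the `liu` flag at extreme significance levels deserve
  a second look.
* Case-only, retrospective-likelihood and subtype-stratified designs are
  out of scope, as are imputation, phasing and liftover.
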