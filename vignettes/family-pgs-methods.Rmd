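---
title: "Methods: family-based polygenic score analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based polygenic score analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

A polygenic score (PGS) is a weighted sum of an individual's effect-allele
dosages, with weights taken from a genome-wide association study in an
independent discovery sample. When a PGS predicts a phenotype in a population
sample, the association can arise through several distinct pathways:

* **direct genetic effects** — the variants influence the phenotype in the
  carrier;
* **indirect genetic effects (genetic nurture)** — parental genotype shapes
  the rearing environment, which influences the child; because parents
  transmit both genes and environment, the child's genotype ends up
  correlated with that environment (passive gene–environment correlation);
* **confounding** — population stratification (allele-frequency differences
  between subpopulations that also differ in the phenotype) and assortative
  mating (phenotypic partner similarity) both inflate population-level PGS
  effects.

Twin-family data can separate these. Dizygotic (DZ) co-twins share parents,
age and family environment, and differ only through the Mendelian lottery of
meiosis, sharing on average half their segregating alleles. Contrasts
*within* DZ pairs are therefore immune to stratification, assortative mating
and any family-level environmental pathway, while contrasts *between*
families absorb all of them. `fampgs` implements this design end to end:
a generative twin-family simulator, PGS construction (including
summary-statistic BLUP reweighting), the covariate-adjusted association
model with cluster-robust inference, the within/between-family
random-intercept decomposition, and correlation-based diagnostics for
gene–environment correlation and confounding.

## The generative model

`sim_config()` + `simulate_twin_study()` generate one twin pair per family
(the within-family estimator uses complete pairs only, so singletons would
be dead weight):

1. **Ancestral frequencies** are uniform on `maf_range` (default 0.1–0.5).
   Subpopulation frequencies diverge by a Balding–Nichols model:
   `Beta(p(1-F)/F, (1-p)(1-F)/F)` with mean `p` and variance `F p(1-p)`.
2. **Parents** are drawn in Hardy–Weinberg proportions per subpopulation;
   with `rho_ld > 0`, haplotypes within equal-sized blocks follow a
   Gaussian-threshold copula with adjacent-variant latent correlation
   `rho_ld`. Loci are unlinked at meiosis even then: parental LD exists only
   so that SBLUP reweighting has something to correct, and unlinked
   transmission keeps meiosis exact and fast.
3. **Mating** acts on the parental *phenotype*, not the PGS: couples are
   rank-matched through a shared latent Gaussian with correlation
   `rho_mate`. The spousal correlation of the genetic value is therefore an
   emergent quantity, reported by the simulator rather than imposed.
4. **Meiosis** transmits one uniformly chosen parental haplotype per locus
   per twin; a monozygotic (MZ) pair duplicates one meiosis, a DZ pair is
   two independent ones. The transmission record keeps the coin flips, so
   identity-by-descent sharing is computable exactly even through
   homozygous parents.
5. **Phenotype**: with `g` the child's standardized true genetic value and
   `g_mid` the standardized mid-parent value,
   `y = delta * g + eta * g_mid + shift[subpop] + c_fam + e`,
   where `c_fam ~ N(0, sigma_c^2)` is shared by co-twins and the residual
   SD is chosen to bring the total variance to 1 (an infeasible budget is
   an error that reports the components). `eta` is the genetic-nurture
   channel; it reaches the child only through the family, so it loads on
   the between-family effect.
6. **Weights**: true per-variant effects are `N(0, h2_true/M)` on the
   standardized-genotype scale; "GWAS" weights add `N(0, gwas_noise_sd^2)`
   estimation noise. This emulates a noisy discovery GWAS without running
   one.
7. **Family-environment items**: a latent enrichment score
   `loading * g_mid + sqrt(1-loading^2) * noise` drives two Poisson counts,
   an ordinal concert-attendance item and a binary early-music-education
   item — the pattern of measures used to index a musically enriched
   childhood home.

Default effect sizes (`delta = 0.35`, `eta = 0`, `sigma_c = 0.3`,
`rho_mate = 0`, `fst = 0`, `prop_mz = 0.4`, `enrichment_loading = 0.5`)
are illustrative of a moderately heritable behavioural trait with a
substantial shared environment; the source cohorts this design mirrors do
not quantify the strength of nurture or assortment, so no attempt is made
to calibrate them, and scenario parameters are always set explicitly in
tests.

### What the simulator does not emulate

Recombination maps and linked meiosis, X-linked variation, multi-
generational equilibrium assortative mating, admixture LD, rare variants,
genotyping error and imputation uncertainty. Passing tests therefore show
that the estimators recover the stated generative quantities under this
idealized design — not that they are robust to everything real cohort data
contain.

## Polygenic scoring

`compute_pgs()` is the standard weighted sum with auditable allele
matching: exact effect/other match keeps the dosage, swapped alleles flip
it (`d -> 2 - d`), strand-ambiguous pairs (A/T, C/G) are dropped, anything
else is a mismatch and dropped; all exclusions are counted. Missing
dosages score at `2 * frequency`, their Hardy–Weinberg expectation. MZ
co-twins missing a score inherit the co-twin's (`impute_mz_pgs()`), which
is exact under MZ genetic identity.

`sblup_reweight()` converts marginal GWAS weights into joint
(best-linear-unbiased-prediction) weights per LD block, solving
`(R + kappa I) b = beta_marginal` with `kappa = lambda/N` and
`lambda = M (1/h2_snp - 1)`. This is algebraically the summary-statistic
form of individual-level ridge regression with penalty `lambda` on
standardized genotypes, which is how the tests validate it: on simulated
individual-level data the SBLUP weights must correlate > 0.99 with an
explicit ridge solve. With `R = I` the formula collapses to uniform
shrinkage `beta/(1 + kappa)`.

## Association and decomposition

`pgs_association()` regresses the standardized outcome on the standardized
PGS plus covariates (canonically sex, age and the top 10 ancestry PCs from
`pca_components()` after `maf_filter()` and `ld_prune()`), with the
clustered sandwich covariance over families — the Stata-style small-sample
factor `G/(G-1) * (n-1)/(n-k)`, so single-observation clusters reduce to
HC1 — and t reference with `G - 1` degrees of freedom. The effect size is
the increment in R² over the covariate-only model. The two fits share rows
(complete cases, with the dropped count reported), and nesting makes the
increment non-negative by construction.

`decompose_pgs()` splits each complete DZ pair's scores into the family
mean and the deviation from it; `fit_family_decomp()` fits

```
Y_ij = a0 + bW (PGS_ij - meanPGS_j) + bB meanPGS_j + covariates + gamma_j + e_ij
```

with a family random intercept. Equal `bW` and `bB` indicate direct
effects; `bB > bW` indicates nurture or confounding. Age is excluded from
the covariates on purpose: co-twins share age exactly, making it collinear
with the family intercept; sex and the PCs are the canonical set.

### REML by one-dimensional profiling

Variance components are estimated by REML rather than ML (the standard
choice for mixed models, removing the downward bias of fixed-effect
estimation from the variance components). The paired structure admits a
closed form: with `theta = var_family / var_resid`, each pair's
`V0^{-1} = I - c J` with `c = theta/(1+2 theta)` and
`log|V0| = n_pairs log(1+2 theta)`, so the criterion
`n_fam log(1+2θ) + (n-p) log(r'V0^{-1}r) + log|X'V0^{-1}X|`
is evaluated in O(n) and minimized over `theta` by `optimize()` on
`[0, 200]`. The `var_family = 0` boundary is explicitly compared and
reported when optimal; running into the upper search bound flags
non-convergence. Fixed effects are GLS at the optimum, SEs come from the
GLS covariance, and 95% CIs are the normal approximation
`estimate ± 1.96 SE`. Tests verify the optimum against a dense
grid-search on the generic matrix form of the same criterion, and the
whole fit (coefficients, SEs, variance components) against `lme4::lmer`,
which is used only as an independent cross-check.

`compare_within_between()` reports `bB - bW` with a Wald z from the joint
GLS covariance, plus the cruder overlapping-CI indicator, since both
readings are common in applied reports. In balanced pairs the two
regressors are exactly orthogonal, so the covariance term is near zero.

## Diagnostics

* `environment_index()`: first principal component of the standardized
  family-environment items (correlation-matrix PCA), sign-oriented so the
  music-education item loads positively. Its correlation with the
  individual PGS (Fisher CI) is the gene–environment-correlation
  diagnostic.
* `dz_pgs_correlation()`: Pearson correlation of co-twin scores over
  complete DZ pairs with a deterministic (lexicographic) twin ordering and
  `n` = number of pairs. Plain Pearson on ordered pairs rather than a
  double-entry intraclass correlation: with pair-level `n` the Fisher CI
  then matches the way such intervals are conventionally reported for this
  diagnostic. The expectation under random mating is 0.50; the verdict
  against 0.50 uses CI bounds rounded to two decimals, boundary inclusive,
  matching how such intervals are read in print.
* `expected_r2()`: the large-sample accuracy approximation
  `h2_snp / (1 + (M/N) h2_snp)`, increasing in the discovery sample size
  `N` and bounded by the SNP heritability.

Fisher intervals use `tanh(atanh(r) ± z/sqrt(n-3))`; their coverage is
checked by simulation (target 95%, accepted band 93–97% over 2000
replicates at n = 200, r = 0.5).

## Numerical and design choices

* **Strict MAF boundary**: "MAF > 0.05" excludes the boundary; the
  computed frequency is rounded at the 12th decimal so binary
  representation noise cannot flip a boundary case.
* **LD pruning** is the PLINK-style greedy left-to-right windowed scan
  (defaults: window 50 variants, step 5), deterministic for a fixed input
  order; zero-variance variants are dropped first with a warning. The
  guarantee is per co-window pair, as for any windowed pruner.
* **PCA sign convention**: each component's largest-magnitude loading is
  made positive, removing eigensolver sign ambiguity. Missing dosages are
  mean-imputed for PCA only; PCA keeps all samples (no outlier-removal
  stage).
* **Two-sided p-values throughout; no multiple-testing adjustment** —
  per-outcome results are reported unadjusted, and the output table makes
  that explicit by carrying every outcome.
* **R² source**: the reported R² comes from the least-squares fit; robust
  covariance changes inference, never point estimates or R².

## A quantitative-genetic note on assortative mating

For a single generation of phenotypic assortment producing a realized
spousal genetic-value correlation `rho`, the co-twin *covariance* is
`(1+rho)/2` times the parental-generation genetic variance, but assortment
also inflates the twin-generation variance to `(2+rho)/2`, so the co-twin
Pearson correlation is `(1+rho)/(2+rho)` — not `0.5 (1+rho)`, which is the
covariance on the parental variance scale. The property test asserts the
Pearson form, verified by brute-force simulation. Relatedly, with a finite
parent pool the co-twins share the pool's chance LD, which adds
`O(1/sqrt(n_families))` noise to score-level co-twin correlations beyond
ordinary pair-sampling error; simulation-based checks of the 0.50
expectation therefore use 20,000 families rather than the minimal 2,000.

## Problem sizes used by the test suite

Simulation checks run at the smallest sizes that keep Monte-Carlo error
well inside each tolerance: 20,000 families for the DZ-correlation
constant, 1,000 pairs × 200 loci for IBD sharing, 200 replicates of 500
pairs per scenario for the direct-vs-nurture discrimination study, 1,000
replicates for the cluster-robust type-I-error calibration and 2,000 for
Fisher-CI coverage. Oracle equivalences (normal equations, dense sandwich,
dense REML grid, individual-level ridge, dense eigensolver) run on small
instances where dense linear algebra is exact.

## Known limitations

The within-family estimator uses complete DZ pairs only, so its power is
governed by the DZ-pair count, not the cohort size. Measurement error in
the PGS attenuates both decomposition coefficients (equally, under the
generative model here). The simulator's stratification is additive and
admixture-free, its assortment is single-generation, and its environment
items are family-constant; none of the reactive/active forms of
gene–environment correlation are generated, and the within-family design
could not separate them anyway.
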