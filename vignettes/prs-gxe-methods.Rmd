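---
title: "Methods: kinship-aware PRS x environment interaction analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinship-aware PRS x environment interaction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
models, the simulator that provides ground truth, the numerical choices,
and the limits of what the test suite demonstrates.

## 1. The analysis model

Cohorts of children measured at up to three visits (baseline, FU1, FU2),
with siblings, are analyzed with generalized linear mixed models whose
random intercept is structured by genome-wide relatedness:

$$ g(E(y)) = X\beta + \gamma, \qquad \gamma \sim N(0,\ \sigma^2_g\, Z V Z^\top), $$

where $V$ is the genetic relatedness matrix over children, and $Z$ maps
each child-visit observation to its child, so one child's visits share a
single random intercept. A single GRM-structured component jointly absorbs
family relatedness and broad population stratification; no principal
components are added. Gaussian outcomes (BMI and waist-circumference
z-scores) use the identity link with an additional iid residual
$\varepsilon \sim N(0, \sigma^2_e I)$; binary outcomes (obesity,
top-quartile waist circumference) use the logit link.

The fixed-effect adjustment set is sex, age (years, linear), region of
residence, parental education, and the fruit/vegetable score as dietary
proxy. Models testing the fiber-density interaction drop the
fruit/vegetable covariate, because both operationalize "healthy diet".
Categorical covariates are dummy-coded against the largest-sample
category, recomputed on each model's complete cases. Missing data are
handled by listwise deletion per model; nothing is imputed. Continuous
exposures are mean-centered before products so the PRS main effect remains
the slope at average exposure (the choice is ours; centering does not
change the interaction coefficient). The PRS is re-standardized over the
retained children, so slopes are per SD of the analysis sample.

## 2. REML through one eigendecomposition

For the Gaussian case the covariance is
$\sigma^2_g\,\Sigma_{obs} + \sigma^2_e I$ with
$\Sigma_{obs} = Z V Z^\top$. Writing $C = Z^\top Z$ (diagonal: visits per
child), the nonzero eigenpairs of $\Sigma_{obs}$ are exactly those of the
$n_{ind}\times n_{ind}$ matrix $C^{1/2} V C^{1/2}$; the orthogonal
complement of $\mathrm{col}(Z)$ is a null space handled through the
projection $I - Z C^{-1} Z^\top$, which enters the likelihood only via
three quadratic forms. This gives the exact restricted likelihood at
$O(n_{ind}^3)$ once plus $O(n_{obs}\,n_{ind}\,p)$ per fit, instead of
$O(n_{obs}^3)$ — the difference between minutes and hours at three visits
per child, and what makes the replicated simulations below affordable.

The restricted likelihood is profiled to the ratio
$\delta = \sigma^2_e/\sigma^2_g$ and maximized on
$\log\delta \in [-10, 10]$ (covering every practically identifiable
ratio) by Brent search, then polished to machine precision with a closed
form for $d\ell/d\log\delta$ and a bracketing root find. Fits are computed
on the unit-SD scale of $y$ and transformed back, so rescaling $y$ by $c$
rescales $\hat\beta$ by $c$ and variance components by $c^2$ exactly.
Boundary solutions ($\hat\sigma^2_g \to 0$ at $\log\delta = 10$, or the
reverse) are legitimate fits and are flagged, not errored; at the upper
boundary the covariance is identity up to $e^{-10}$, so coefficients agree
with OLS to about $10^{-4}$. REML is the default criterion (unbiased
variance components under the fixed-effect projection); ML is available
via `method = "ML"`. A dense $O(n^3)$ `loglik_oracle()` in the identical
likelihood convention (including the $-\log|X^\top X|$ REML term) exists
purely as an independent cross-check; the test suite holds the two paths
to $10^{-8}$.

Binary outcomes use penalized quasi-likelihood: iterating a weighted
working linear mixed model with covariance
$\sigma^2_g \Sigma_{obs} + W^{-1}$, where the weight matrix changes each
iteration, so the reduction above is re-applied with $C = Z^\top W Z$
(still diagonal). The binomial dispersion is fixed at 1 and only
$\sigma^2_g$ is profiled. The fixed-point iteration converges linearly and
occasionally very slowly; an Aitken extrapolation step on the linear
predictor (bounded gain, fixed points unchanged) accelerates it, and the
rare fit that still moves more than $10^{-6}$ per iteration after 50
iterations is returned flagged `converged = FALSE` with a warning. PQL is
known to bias $\hat\sigma^2_g$ toward zero for rare binary outcomes; the
package reports odds ratios, whose bias at the ~7% prevalence used here
is modest, and the Gaussian analyses carry the calibration burden.

Wald inference throughout: $z = \hat\beta/SE$, two-sided normal p values,
and 95% CIs computed as $\hat\beta \pm 1.96\,SE$ exactly.
Benjamini–Hochberg q-values are computed by an explicit step-up
implementation across all interaction contrasts within one outcome —
contrasts of multi-level factors counted individually, since stratified
reporting is per contrast; the family definition is configurable.

Two constructions are ours because the source analyses leave them
unspecified: the incremental $r^2$ of the PRS is computed on the whitened
scale (response and design transformed by the full model's fitted
covariance, then $(RSS_{red}-RSS_{full})/RSS_{red}$), and the AUC is the
Mann–Whitney statistic of the fixed-effect linear predictor at observation
level. Whitened $r^2$ is smaller than a marginal variance share whenever
the GRM component absorbs part of the polygenic signal; the two should not
be compared across definitions.

## 3. PRS construction

Weights are harmonized to the VCF dosage convention (dosage = ALT count):
effect/other equal to alt/ref keeps the weight, ref/alt negates it,
palindromic A/T and C/G pairs are dropped by default (strand unknown in
general VCFs; the flag can be disabled for simulated data where strand is
known), and mismatched allele pairs are dropped — all counted in an audit
log. Scores are dosage-weighted sums with missing dosages imputed at twice
the sample ALT frequency. The top PRS decile is computed on the analysis
sample itself, not an external reference.

LDpred-style reweighting is implemented in its infinitesimal closed form,
per LD block: $\beta_{post} = (D + \frac{M}{N h^2} I)^{-1}\beta_{marg}$,
with $D$ the block LD matrix, $M$ the number of scored variants, $N$ the
GWAS sample size. The ridge term is strictly positive so the solve always
exists, and at $D = I$ it reduces to elementwise shrinkage by
$1/(1 + M/(N h^2))$. The point-normal sparsity prior (Gibbs sampler) is
deliberately out of scope; its "proportion causal" notion lives on in the
simulator's architecture. Sensitivity-style scores are provided as
simplified clumping+thresholding (greedy by ascending p within an LD-block
or base-pair window, $r^2$ capped against kept variants) and a
genome-wide-significance filter at $5\times10^{-8}$.

## 4. The synthetic family cohort

The generator emulates a pan-European childhood cohort with repeated
measurements and sibling structure; all defaults are the study conditions
its tests assume.

**Pedigrees and genotypes.** Nuclear families: two founders plus a fixed
number of offspring, sex Bernoulli(0.5). Founder haplotypes come from a
latent-Gaussian AR(1) threshold model within fixed-size blocks
(correlation `ld_rho`, default 0.6, block size 25, MAF uniform on
[0.05, 0.5]), independent across blocks; offspring are gene-dropped with
recombination only at block boundaries. This is not a human LD map — it is
the minimal structure with tunable LD for exercising LD-aware reweighting
and realistic kinship (sib and parent-offspring standardized relatedness
center on 0.5).

**Causal architecture.** Point-normal effects: causal with probability
`p_causal` (default 0.01), effect variance $h^2/(M\,p_{causal})$ so the
standardized genetic values have variance $h^2$ (default 0.5).

**Exposures.** Region (Central/North/South, 41/25/34%) and parental
education (low/medium/high, 6/44/50%) are family-level; fruit/veg score
(mean 14.66, SD 7.49%), fiber density (8.17, 1.31 mg/kcal), MVPA (0.67,
0.36 h/day) and screen time (1.60, 1.00 h/day, truncated to [0, 8]) are
child-visit-level, matching the cohort's published baseline marginals.
Exposures are generated independent of genotype: the source analyses treat
these factors as effect modifiers, not as genetically correlated
covariates, and report no gene-environment correlations to emulate — this
assumption is the generator's, flagged here. Missingness defaults to 0;
per-exposure missingness rates reproduce the cohort's missing-data pattern
when switched on, and masking happens after outcome generation so the true
model is untouched. An education-shifts-PRS confounding knob exists but
defaults to off.

**Outcomes.** Ages start Uniform(2, 9.9) years and advance by +2 and +4
years with N(0, 0.3) jitter. The continuous outcome is
$y = \beta_0 + \beta_{age}a + \beta_{sex}s + \sum\beta_E E + \text{slope}(E)\,S + \gamma + \varepsilon$
with $\text{slope}(E) = \beta_{prs} + \sum\beta_{g\times e}[E]\,E$
(continuous exposures centered at generator means),
$\gamma \sim N(0, \sigma^2_g V)$ from the realized GRM of the simulated
children, and defaults $\sigma^2_g = 0.4$, $\sigma^2_e = 0.6$. Binary
outcomes threshold an independent latent copy at an empirical prevalence
quantile (7% obesity, 14% top-quartile waist circumference).

**Interaction defaults.** The reference-condition slope is 0.26/SD with
education low +0.18 and medium +0.05, region South +0.11, fiber −0.02 per
SD·(mg/kcal) and screen time +0.02 per SD·(h/day); sex, MVPA and
fruit/veg interactions are 0. These are chosen so that simultaneously the
population-average PRS slope is ≈0.33/SD, the education-stratified slopes
are ≈0.48 (low) vs ≈0.30 (high), and the region-stratified slopes ≈0.40
(South) vs ≈0.29 (Central) — the constellation of published estimates the
simulator is calibrated to. Setting `beta_gxe` to zeros yields exact-null
cohorts for calibration studies.

## 5. What the simulations show — and what they cannot

The replicated studies in the test suite and `scripts/acceptance.R` use
these problem sizes, chosen as the smallest scales at which the quantities
are statistically meaningful: 150 sib-pair families × 3 visits × 2000 SNPs
for variance-ratio recovery (100 replicates, mean within ±0.05 of 0.4) and
interaction type-I error (500 replicates, Wald rejection within the
binomial band around 0.05, with the kinship-ignoring OLS refit inflating
markedly for family-constant exposures); 1500 families (3000 children,
9000 observations) for CI coverage of the fiber interaction and the
low-vs-high education slope ordering (100 replicates); 75 families × 200
replicates for the all-null FDR family-wise discovery rate. Genotypes and
kinship are held fixed across phenotype replicates (inference is
conditional on the genotypes anyway), which is also what lets one
eigendecomposition serve a whole replicate set.

Passing these does not demonstrate performance on real cohort data: the
generator has no real LD map, no genotyping error or imputation
uncertainty, linear age effects, Gaussian exposures, missingness
completely at random when enabled, and exposures independent of genotype.
Coverage of the fiber interaction sits near the lower end of its band
because each fitted model omits the other true interactions — a
misspecification the analysis design shares with single-exposure testing
generally.

## 6. Numerical choices and degenerate inputs

* Monomorphic variants standardize to zero columns and are excluded from
  the GRM by the MAF filter (default 0.01); GRMs are symmetrized and, via
  `make_psd()`, eigenvalue-clamped at $10^{-8}$ with the adjustment
  recorded and the eigensystem cached for reuse.
* `kinship_eigen()` has a diagonal fast path (identity covariance costs
  $O(n)$, not $O(n^3)$).
* The LMS z-score uses the $\log$ form below $|L| < 10^{-12}$; L, M, S and
  cutoffs are linearly interpolated on the age grid per sex with no
  extrapolation (out-of-grid ages are errors). Reference tables are
  consumed as user-supplied TSVs; the package ships only a small synthetic
  reference for its simulated pipeline, since growth references are
  third-party data.
* Screen time uses the 5:2 weekday:weekend weighting (the standard week
  structure; configurable) capped at 8 h/day; MVPA uses the 2296
  counts/min cutpoint (the established children's threshold; configurable)
  with ≥3 valid days of ≥360 worn minutes.
* Degenerate cases fail loudly with classed conditions: rank-deficient
  designs name the collinear columns, zero-variance scores refuse to
  standardize, all-equal binary outcomes refuse to fit, empty
  complete-case sets report per-column missingness.
* Determinism: every stochastic stage takes a seed; `simulate_cohort()`
  derives stage sub-seeds from one global seed, and two runs with the same
  configuration are byte-identical.

## 7. Known limitations

Single variance component (no separate household/visit components, no
leave-one-chromosome-out GRM); PQL rather than higher-order quadrature for
binary outcomes; no score tests or small-sample degree-of-freedom
corrections; dense matrices throughout, targeting cohorts up to roughly
5000 individuals; VCF is the only genotype format.
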