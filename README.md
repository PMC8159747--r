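# prsgxe

Polygenic score × environment interaction analysis for family cohorts with
repeated measurements.

## The problem

Childhood obesity reflects both a polygenic predisposition and the
environment a child grows up in. Testing whether the environment *modifies*
the genetic effect — a gene–environment (G×E) interaction — in a real
pediatric cohort runs into three statistical obstacles at once:

1. the genetic signal is spread over millions of variants, so it must be
   aggregated into a genome-wide **polygenic risk score (PRS)** with
   LD-aware weights;
2. cohort children are **related** (siblings) and were measured **up to
   three times** (baseline and two follow-ups), so observations are
   correlated both between and within individuals;
3. many environmental factors are tested at once, so inference needs
   **false-discovery-rate** control.

`prsgxe` implements this analysis end to end for epidemiologists and
statistical geneticists, together with a family-cohort simulator with known
ground truth so that every stage is testable without access to individual-
level cohort data.

## The model

For outcome `y` (BMI or waist-circumference z-score, or their dichotomized
versions), with link `g`:

```
g(E(y)) = X beta + gamma,     gamma ~ N(0, sigma2_g * Z V Z')
```

* `V` is a genetic relatedness matrix (GRM) estimated from genome-wide
  dosages, `V = Z_g Z_g' / M` with column-standardized genotypes — the
  random intercept simultaneously controls relatedness and population
  stratification;
* `Z` is the observation→individual incidence matrix, so all visits of one
  child share one random intercept;
* `X` contains sex, age, region of residence, parental education, the
  fruit/vegetable score, the standardized PRS `S`, and — for interaction
  models — a product term `S × E`;
* Gaussian outcomes are fitted by **REML**: after one eigendecomposition
  the restricted likelihood is profiled down to the variance ratio
  `delta = sigma2_e / sigma2_g` and maximized by 1-D search; binary
  outcomes use **penalized quasi-likelihood (PQL)** with the same
  machinery;
* each interaction coefficient gets a Wald test; Benjamini–Hochberg
  q-values are computed across the environmental contrasts per outcome;
  categorical interactions are complemented by **stratified PRS slopes**.

PRS construction supports effect-allele harmonization to VCF dosages,
LDpred-inf reweighting (`beta_post = (D + M/(N h2) I)^{-1} beta_marginal`
per LD block), clumping + thresholding, and genome-wide-significant-only
subsets.

## Worked example

Simulate a cohort of 600 children in 300 families (sib pairs, three visits,
2000 SNPs in LD blocks), score the true polygenic values, and run the full
analysis:

```r
library(prsgxe)

co  <- simulate_cohort(n_families = 300, n_snps = 2000, seed = 1)
prs <- standardize_prs(tibble::tibble(
  individual_id = names(co$truth$prs_true),
  score         = co$truth$prs_true))
kin <- make_psd(grm_standardized(
  subset_individuals(co$genotypes, unique(co$pheno$child_id))))

main_effect_analysis(co$pheno, prs, kin,
                     plan = analysis_plan(outcomes = "bmi_z"))
#> # A tibble: 2 × 11
#>   outcome prs_scale  type       estimate conf.low conf.high  p.value     r2   auc n_obs n_children
#> 1 bmi_z   z          continuous    0.334    0.268     0.400 4.05e-23 0.0519    NA  1800        600
#> 2 bmi_z   top_decile continuous    0.567    0.346     0.788 4.76e- 7 0.0140    NA  1800        600
```

The continuous-PRS row says: one standard deviation of the score shifts the
BMI z-score by 0.33 (95% CI 0.27–0.40) after adjusting for sex, age,
region, parental education and diet — matching the generator's
population-average slope of 0.33. The top-decile row is the extra shift for
children in the highest PRS decile. `r2` is the incremental share of
whitened residual variation the PRS explains on top of the covariates.

```r
interaction_analysis(co$pheno, prs, kin,
                     plan = analysis_plan(outcomes = "bmi_z",
                                          exposures = c("fiber", "education")))
#> # A tibble: 3 × 11
#>   outcome exposure  n_obs term                estimate     se conf.low conf.high statistic p.value q.value
#> 1 bmi_z   fiber      1800 fiber:prs            -0.0337 0.0154  -0.0640  -0.00344    -2.18   0.0290  0.0871
#> 2 bmi_z   education  1800 educationlow:prs      0.198  0.127   -0.0499   0.446       1.57   0.118   0.176
#> 3 bmi_z   education  1800 educationmedium:prs   0.0154 0.0640  -0.110    0.141       0.242  0.809   0.809
```

The fiber product term (−0.034, raw p 0.029) has the generator's negative
sign (truth −0.02 per SD·(mg/kcal)) but does not survive FDR adjustment
across the three contrasts at this modest sample size; the low-education
contrast points the right way (+0.20, truth +0.18) with a wide CI. Both
reach significance at the full cohort scale exercised by the acceptance
script.

```r
s <- stratified_analysis(co$pheno, prs, kin, "bmi_z", "education")
autoplot(s, overall = 0.33)   # forest plot of per-stratum PRS slopes
```

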