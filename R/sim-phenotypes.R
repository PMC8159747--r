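#' Simulate per-variant causal effects (point-normal architecture)
#'
#' With probability `p_causal` a variant is causal and its effect (on the
#' standardized-dosage scale) is drawn from Normal(0, h2 / (n_snps * p_causal));
#' otherwise the effect is exactly 0. With standardized dosages the genetic
#' values then have variance ~ `h2`.
#'
#' @param n_snps Number of variants.
#' @param p_causal Proportion of causal variants in `(0, 1]`.
#' @param h2 Variance of the genetic value in `[0, 1)`.
#' @param seed Integer seed.
#' @return Tibble with `id` (variant index), `beta`, `causal`.
#' @export
simulate_effects <- function(n_snps, p_causal = 0.01, h2 = 0.5, seed = 1L) {
  if (p_causal <= 0 || p_causal > 1) stop_invalid("p_causal must be in (0, 1]")
  if (h2 < 0 || h2 >= 1) stop_invalid("h2 must be in [0, 1)")
  set.seed(seed)
  causal <- stats::rbinom(n_snps, 1L, p_causal) == 1L
  beta <- numeric(n_snps)
  if (h2 > 0 && any(causal)) {
    beta[causal] <- rnorm(sum(causal), 0, sqrt(h2 / (n_snps * p_causal)))
  }
  tibble::tibble(id = seq_len(n_snps), beta = beta, causal = causal)
}

#' Default exposure-generator settings
#'
#' Marginal means/SDs follow the baseline survey of a pan-European childhood
#' cohort: fruit/veg score 14.66 (7.49) percent, fiber density 8.17 (1.31)
#' mg/kcal, MVPA 0.67 (0.36) h/day, screen time 1.60 (1.00) h/day; region
#' shares Central/North/South roughly 41/25/34 percent and parental education
#' low/medium/high 6/44/50 percent. Missingness defaults to 0 for every
#' exposure (a per-exposure `missing` rate switches it on).
#'
#' @return A named list of exposure settings.
#' @export
default_exposure_params <- function() {
  list(
    region_probs = c(Central = 0.414, North = 0.246, South = 0.339),
    education_probs = c(low = 0.0597, medium = 0.4433, high = 0.4851),
    fruit_veg = list(mean = 14.66, sd = 7.49, min = 0, max = 100, missing = 0),
    fiber = list(mean = 8.17, sd = 1.31, min = 0, max = Inf, missing = 0),
    mvpa = list(mean = 0.67, sd = 0.36, min = 0, max = Inf, missing = 0),
    screen_time = list(mean = 1.60, sd = 1.00, min = 0, max = 8, missing = 0)
  )
}

#' Simulate sociodemographic and lifestyle exposures
#'
#' Region and parental education are drawn once per family (all siblings
#' share them); the lifestyle exposures are drawn per child-visit,
#' independent of genotype (no gene-environment correlation by default).
#' Continuous exposures are truncated to their plausible ranges.
#'
#' @param pedigree Pedigree tibble; exposures are generated for offspring.
#' @param exposure_params Settings, see [default_exposure_params()].
#' @param n_visits Visits per child (1-3).
#' @param seed Integer seed.
#' @return Long tibble, one row per child-visit: `child_id`, `family_id`,
#'   `visit`, `region`, `education`, `fruit_veg`, `fiber`, `mvpa`,
#'   `screen_time`.
#' @export
simulate_exposures <- function(pedigree, exposure_params = default_exposure_params(),
                               n_visits = 3L, seed = 1L) {
  validate_pedigree(pedigree)
  if (n_visits < 1 || n_visits > 3) stop_invalid("n_visits must be 1, 2 or 3")
  set.seed(seed)
  p <- exposure_params
  kids <- pedigree[pedigree$role == "offspring", ]
  fams <- unique(kids$family_id)
  fam_region <- sample(names(p$region_probs), length(fams), TRUE, p$region_probs)
  fam_edu <- sample(names(p$education_probs), length(fams), TRUE, p$education_probs)
  names(fam_region) <- names(fam_edu) <- fams

  visits <- c("baseline", "FU1", "FU2")[seq_len(n_visits)]
  out <- tidyr::expand_grid(child_id = kids$individual_id, visit = visits)
  idx <- match(out$child_id, kids$individual_id)
  out$family_id <- kids$family_id[idx]
  out$sex <- kids$sex[idx]
  out$region <- factor(unname(fam_region[out$family_id]),
                       levels = c("Central", "North", "South"))
  out$education <- factor(unname(fam_edu[out$family_id]),
                          levels = c("low", "medium", "high"))
  n <- nrow(out)
  draw <- function(cfg) pmin(pmax(rnorm(n, cfg$mean, cfg$sd), cfg$min), cfg$max)
  out$fruit_veg <- draw(p$fruit_veg)
  out$fiber <- draw(p$fiber)
  out$mvpa <- draw(p$mvpa)
  out$screen_time <- draw(p$screen_time)
  out <- dplyr::select(out, "child_id", "family_id", "visit", "sex",
                       dplyr::everything())
  miss <- vapply(c("fruit_veg", "fiber", "mvpa", "screen_time"),
                 function(v) p[[v]]$missing, numeric(1))
  if (any(miss > 0)) {
    complete <- out
    for (v in names(miss)[miss > 0]) {
      out[[v]][runif(n) < miss[[v]]] <- NA_real_
    }
    # the unmasked values remain available to the phenotype generator, so
    # missingness hides data without perturbing the true outcome model
    attr(out, "complete") <- complete
  }
  out
}

#' Default fixed-effect and interaction settings for the phenotype simulator
#'
#' The PRS slope at reference conditions (high education, Central region,
#' mean-centered continuous exposures) is 0.26 per SD of the score; with the
#' default interaction profile (education low +0.18, medium +0.05; region
#' South +0.11; fiber -0.02 per mg/kcal; screen time +0.02 per h/day) the
#' population-average slope is ~0.33 per SD, the education-stratified slopes
#' are ~0.48 (low) vs ~0.30 (high) and the region-stratified slopes ~0.29
#' (Central) vs ~0.40 (South). Setting all interaction entries to 0 yields a
#' null-interaction cohort.
#'
#' @return Named list of generator coefficients.
#' @export
default_effect_params <- function() {
  list(
    intercept = 0.2,
    age = 0.03,            # per year, z-score outcome drifts mildly upward
    sex = 0,               # outcomes are sex-standardized z-scores
    region = c(North = -0.05, South = 0.1),      # vs Central
    education = c(low = 0.15, medium = 0.05),    # vs high
    fruit_veg = -0.005, fiber = -0.03, mvpa = -0.1, screen_time = 0.05,
    beta_prs = 0.26,
    beta_gxe = list(
      education = c(low = 0.18, medium = 0.05),
      region = c(North = 0, South = 0.11),
      sex = 0, fruit_veg = 0, fiber = -0.02, mvpa = 0, screen_time = 0.02
    )
  )
}

#' Simulate repeated anthropometric phenotypes with known ground truth
#'
#' One row per child-visit. The continuous outcome is
#' `y = b0 + b_age age + b_sex sex + sum(b_E E) + slope(E) * S + gamma + eps`
#' where `S` is the standardized true polygenic value,
#' `slope(E) = beta_prs + sum(beta_gxe[E] * E)` (continuous exposures centered
#' at their generator means), `gamma ~ N(0, sigma2_g V)` is an
#' individual-level random intercept with `V` the standardized genetic
#' relatedness matrix of the simulated children (shared across a child's
#' visits), and `eps ~ N(0, sigma2_e)` iid. A second outcome (waist z-score
#' analogue) reuses `gamma` with its own coefficients and residuals. Binary
#' outcomes threshold an independent latent copy of each outcome at an
#' empirical prevalence quantile. Ages start Uniform(2, 9.9) and advance by
#' about +2 and +4 years at follow-ups (N(0, 0.3) jitter).
#'
#' @param genotypes `genotype_matrix` covering at least the children.
#' @param effects Tibble from [simulate_effects()] (columns `id`, `beta`).
#' @param exposures Exposure tibble from [simulate_exposures()].
#' @param sigma2_g,sigma2_e Variance components of the random intercept and
#'   the residual.
#' @param effect_params See [default_effect_params()].
#' @param wc_params Coefficients for the second outcome; defaults to
#'   `effect_params` with `beta_prs = 0.29` and fiber interaction -0.03.
#' @param prevalence Prevalence for each binary outcome
#'   (`c(obese = 0.07, wc_top = 0.14)`).
#' @param attrition Per-follow-up dropout probability (visit 2 kept with
#'   probability `1 - attrition`, visit 3 with `(1 - attrition)^2`).
#' @param seed Integer seed.
#' @param kinship Optional precomputed PSD `kinship` over exactly the
#'   exposure children (e.g. from [make_psd()], whose eigensystem is then
#'   reused); `NULL` computes it from the genotypes.
#' @return List with `pheno` (tibble: child_id, family_id, visit, age, sex,
#'   region, education, exposures, bmi_z, wc_z, obese, wc_top) and `truth`
#'   (list: per-variant effects, genetic values, standardized score `S`,
#'   `gamma`, variance components, coefficient lists).
#' @export
simulate_phenotypes <- function(genotypes, effects, exposures,
                                sigma2_g = 0.4, sigma2_e = 0.6,
                                effect_params = default_effect_params(),
                                wc_params = NULL,
                                prevalence = c(obese = 0.07, wc_top = 0.14),
                                attrition = 0, seed = 1L, kinship = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (nrow(effects) != ncol(genotypes$dosage)) {
    stop_invalid("effects and genotypes disagree on the number of variants")
  }
  children <- unique(exposures$child_id)
  if (!all(children %in% rownames(genotypes$dosage))) {
    stop_invalid("exposure table contains children missing from the genotypes")
  }
  if (sigma2_g < 0 || sigma2_e < 0) stop_invalid("variance components must be >= 0")
  set.seed(seed)

  if (is.null(wc_params)) {
    wc_params <- effect_params
    wc_params$beta_prs <- 0.29
    wc_params$beta_gxe$fiber <- -0.03
  }

  # true genetic value and standardized score over the analysis children
  Z <- standardize_dosage(genotypes$dosage[children, , drop = FALSE])
  g <- drop(Z %*% effects$beta)
  S <- if (sd(g) > 0) (g - mean(g)) / sd(g) else g * 0
  names(g) <- names(S) <- children

  # kinship-structured random intercept, one value per child; a precomputed
  # PSD kinship (with its eigensystem attached by make_psd) avoids repeating
  # the eigendecomposition across simulation replicates
  gamma <- numeric(length(children))
  if (sigma2_g > 0) {
    if (is.null(kinship)) {
      kinship <- make_psd(grm_standardized(subset_individuals(genotypes, children)))
    }
    if (!identical(kinship$ids, children)) {
      stop_invalid("supplied kinship must cover exactly the exposure children, same order")
    }
    ev <- attr(kinship, "eigen")
    if (is.null(ev)) ev <- eigen(kinship$matrix, symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    gamma <- drop(ev$vectors %*% (sqrt(sigma2_g * lam) * rnorm(length(children))))
  }
  names(gamma) <- children

  ph <- exposures
  # complete (pre-masking) exposure values drive the true model; the masked
  # copy is what the analyst sees
  comp <- attr(exposures, "complete") %||% exposures
  n_kid <- length(children)
  base_age <- runif(n_kid, 2, 9.9)
  names(base_age) <- children
  offs <- c(baseline = 0, FU1 = 2, FU2 = 4)
  ph$age <- base_age[ph$child_id] + offs[ph$visit] +
    ifelse(ph$visit == "baseline", 0, rnorm(nrow(ph), 0, 0.3))
  comp$age <- ph$age

  # 0 for factor levels without a declared coefficient
  lev_coef <- function(vec, labels) {
    full <- stats::setNames(rep(0, nlevels(labels)), levels(labels))
    full[names(vec)] <- vec
    unname(full[as.character(labels)])
  }
  ctr <- default_exposure_params()
  lp_for <- function(params) {
    slope <- params$beta_prs +
      lev_coef(params$beta_gxe$education, comp$education) +
      lev_coef(params$beta_gxe$region, comp$region) +
      params$beta_gxe$sex * (comp$sex == "M") +
      params$beta_gxe$fruit_veg * (comp$fruit_veg - ctr$fruit_veg$mean) +
      params$beta_gxe$fiber * (comp$fiber - ctr$fiber$mean) +
      params$beta_gxe$mvpa * (comp$mvpa - ctr$mvpa$mean) +
      params$beta_gxe$screen_time * (comp$screen_time - ctr$screen_time$mean)
    fx <- params$intercept + params$age * comp$age +
      params$sex * (comp$sex == "M") +
      lev_coef(params$region, comp$region) +
      lev_coef(params$education, comp$education) +
      params$fruit_veg * (comp$fruit_veg - ctr$fruit_veg$mean) +
      params$fiber * (comp$fiber - ctr$fiber$mean) +
      params$mvpa * (comp$mvpa - ctr$mvpa$mean) +
      params$screen_time * (comp$screen_time - ctr$screen_time$mean)
    list(fixed = fx, slope = slope)
  }
  n_obs <- nrow(ph)
  mk_outcome <- function(params) {
    parts <- lp_for(params)
    mu <- parts$fixed + parts$slope * S[ph$child_id] + gamma[ph$child_id]
    cont <- mu + rnorm(n_obs, 0, sqrt(sigma2_e))
    latent <- mu + rnorm(n_obs, 0, sqrt(sigma2_e))
    list(cont = cont, latent = latent)
  }
  bmi <- mk_outcome(effect_params)
  wc <- mk_outcome(wc_params)
  ph$bmi_z <- bmi$cont
  ph$wc_z <- wc$cont
  ph$obese <- as.integer(bmi$latent >= quantile(bmi$latent, 1 - prevalence[["obese"]]))
  ph$wc_top <- as.integer(wc$latent >= quantile(wc$latent, 1 - prevalence[["wc_top"]]))

  if (attrition > 0) {
    keep_p <- (1 - attrition)^(match(ph$visit, names(offs)) - 1)
    ph <- ph[runif(n_obs) <= keep_p, , drop = FALSE]
  }

  truth <- list(
    effects = effects, genetic_value = g, prs_true = S, gamma = gamma,
    sigma2_g = sigma2_g, sigma2_e = sigma2_e,
    effect_params = effect_params, wc_params = wc_params,
    prevalence = prevalence
  )
  list(pheno = tibble::as_tibble(ph), truth = truth)
}

#' Simulate a complete family cohort
#'
#' Convenience wrapper chaining pedigree, genotypes, causal effects,
#' exposures and phenotypes under one configuration with a single seed
#' (stage-specific sub-seeds are derived from it).
#'
#' @param n_families,offspring_per_family Pedigree shape.
#' @param n_snps,block_size,ld_rho,maf_range Genotype settings.
#' @param p_causal,h2 Causal architecture.
#' @param sigma2_g,sigma2_e Variance components.
#' @param effect_params,wc_params,prevalence,attrition,exposure_params,n_visits
#'   Passed through to the stage generators.
#' @param seed Global integer seed.
#' @return List with `pedigree`, `genotypes`, `effects`, `exposures`,
#'   `pheno`, `truth`.
#' @export
simulate_cohort <- function(n_families = 100, offspring_per_family = 2,
                            n_snps = 1000, block_size = 25, ld_rho = 0.6,
                            maf_range = c(0.05, 0.5), p_causal = 0.01,
                            h2 = 0.5, sigma2_g = 0.4, sigma2_e = 0.6,
                            effect_params = default_effect_params(),
                            wc_params = NULL,
                            prevalence = c(obese = 0.07, wc_top = 0.14),
                            attrition = 0,
                            exposure_params = default_exposure_params(),
                            n_visits = 3, seed = 1L) {
  ped <- simulate_pedigree(n_families, offspring_per_family,
                           seed = derive_seed(seed, "pedigree"))
  geno <- simulate_genotypes(ped, n_snps, block_size, ld_rho, maf_range,
                             seed = derive_seed(seed, "genotypes"))
  eff <- simulate_effects(n_snps, p_causal, h2, seed = derive_seed(seed, "effects"))
  expo <- simulate_exposures(ped, exposure_params, n_visits,
                             seed = derive_seed(seed, "exposures"))
  phe <- simulate_phenotypes(geno, eff, expo, sigma2_g, sigma2_e,
                             effect_params, wc_params, prevalence, attrition,
                             seed = derive_seed(seed, "phenotypes"))
  list(pedigree = ped, genotypes = geno, effects = eff, exposures = expo,
       pheno = phe$pheno, truth = phe$truth)
}

#' Simulate marginal GWAS summary statistics on a founder panel
#'
#' Generates a quantitative trait `y = g + e` on an independent panel
#' (founders of a fresh pedigree) with genetic values from the supplied
#' per-variant effects, then computes per-SNP marginal regressions of the
#' trait on dosage. Returns a weight-table-shaped tibble usable as GWAS
#' input for PRS construction.
#'
#' @param genotypes `genotype_matrix` for the panel individuals.
#' @param effects Tibble from [simulate_effects()].
#' @param h2 Variance of the genetic value (residual variance is `1 - h2`).
#' @param seed Integer seed.
#' @return Tibble: `chrom`, `pos`, `effect_allele` (ALT), `other_allele`
#'   (REF), `weight` (= marginal beta), `beta`, `se`, `p`, `n`.
#' @export
simulate_gwas <- function(genotypes, effects, h2 = 0.5, seed = 1L) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  set.seed(seed)
  X <- genotypes$dosage
  n <- nrow(X)
  Z <- standardize_dosage(X)
  g <- drop(Z %*% effects$beta)
  y <- g + rnorm(n, 0, sqrt(max(1 - h2, 1e-8)))
  xm <- colMeans(X)
  xc <- sweep(X, 2, xm)
  sxx <- colSums(xc^2)
  sxy <- drop(crossprod(xc, y - mean(y)))
  beta <- ifelse(sxx > 0, sxy / sxx, 0)
  rss <- sum((y - mean(y))^2) - beta^2 * sxx
  se <- ifelse(sxx > 0, sqrt(pmax(rss, 0) / ((n - 2) * sxx)), Inf)
  p <- 2 * pnorm(-abs(beta / se))
  v <- genotypes$variants
  tibble::tibble(
    chrom = v$chrom, pos = v$pos,
    effect_allele = v$alt, other_allele = v$ref,
    weight = beta, beta = beta, se = se, p = p, n = n
  )
}
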