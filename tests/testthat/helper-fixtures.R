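# Shared fixtures, built in code. Kept small; heavier simulations live in
# the tests that need them.

make_small_cohort <- function(n_families = 25, n_snps = 400, seed = 11, ...) {
  simulate_cohort(n_families = n_families, offspring_per_family = 2,
                  n_snps = n_snps, block_size = 20, ld_rho = 0.5,
                  p_causal = 0.05, seed = seed, ...)
}

truth_prs <- function(cohort) {
  standardize_prs(tibble::tibble(
    individual_id = names(cohort$truth$prs_true),
    score = cohort$truth$prs_true
  ))
}

# cutoff reference anchored at the published age-6 values, linear elsewhere
toy_bmi_cutoffs <- function() {
  validate_reference_table(tibble::tibble(
    sex = rep(c("M", "F"), each = 3),
    age_years = rep(c(2, 6, 16), 2),
    cutoff = c(18.4, 19.76, 28.9, 18.0, 19.62, 28.6)
  ))
}

toy_wc_cutoffs <- function() {
  validate_reference_table(tibble::tibble(
    sex = rep(c("M", "F"), each = 3),
    age_years = rep(c(2, 6, 16), 2),
    cutoff = c(50.1, 58.3, 81.0, 49.5, 57.2, 79.0)
  ))
}

toy_lms_reference <- function() {
  validate_reference_table(tibble::tibble(
    sex = rep(c("M", "F"), each = 3),
    age_years = rep(c(2, 6, 16), 2),
    L = c(-1.6, -2.0, -1.9, -1.5, -2.1, -2.0),
    M = c(16.5, 15.5, 20.0, 16.2, 15.2, 20.3),
    S = c(0.08, 0.09, 0.12, 0.08, 0.10, 0.12)
  ))
}

# independent dense-REML oracle fixture generator for mixed-model tests
random_related_fixture <- function(seed, n_fam = 4, p = 3) {
  set.seed(seed)
  ped <- simulate_pedigree(n_fam, 2, seed = seed)
  g <- simulate_genotypes(ped, 400, 20, 0.5, c(0.1, 0.5), seed = seed + 1000)
  kids <- ped$individual_id[ped$role == "offspring"]
  kin <- make_psd(grm_standardized(subset_individuals(g, kids)))
  visits <- sample(2:3, 1)
  obs <- rep(kids, each = visits)
  n <- length(obs)
  X <- cbind(intercept = 1,
             matrix(rnorm(n * (p - 1)), n,
                    dimnames = list(NULL, paste0("x", seq_len(p - 1)))))
  Sig <- expand_to_observations(kin, obs)
  L <- t(chol(0.6 * Sig + 0.8 * diag(n)))
  y <- drop(L %*% rnorm(n)) + drop(X %*% runif(p, -1, 1))
  list(y = y, X = X, kin = kin, obs = obs, Sig = Sig)
}
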