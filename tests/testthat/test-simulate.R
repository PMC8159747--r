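test_that("pedigree structure, counting and determinism", {
  ped <- simulate_pedigree(1, 2, seed = 1)
  expect_equal(nrow(ped), 4)
  kids <- ped[ped$role == "offspring", ]
  expect_equal(nrow(kids), 2)
  expect_length(unique(kids$father_id), 1)
  expect_length(unique(kids$mother_id), 1)

  big <- simulate_pedigree(100, 2, seed = 7)
  expect_equal(nrow(big), 400)
  expect_equal(sum(big$role == "founder"), 200)

  expect_identical(simulate_pedigree(3, 1, seed = 5),
                   simulate_pedigree(3, 1, seed = 5))
  expect_error(simulate_pedigree(0, 2), class = "prsgxe_invalid_argument")
})

test_that("genotypes: LD, dosage range, gene-dropping relatedness", {
  ped <- simulate_pedigree(500, 1, seed = 2)
  founders <- ped$individual_id[ped$role == "founder"]
  g0 <- simulate_genotypes(ped, 200, 10, ld_rho = 0, seed = 3)
  X <- g0$dosage[founders, ]
  expect_true(all(X %in% 0:2))
  # rho = 0: inter-SNP dosage correlation near zero at 1000 founders
  cors <- sapply(seq(1, 191, by = 10), function(j) cor(X[, j], X[, j + 1]))
  expect_true(max(abs(cors)) < 0.1)

  g6 <- simulate_genotypes(ped, 200, 10, ld_rho = 0.9, seed = 3)
  X6 <- g6$dosage[founders, ]
  cors6 <- sapply(seq(1, 191, by = 10), function(j) cor(X6[, j], X6[, j + 1]))
  expect_gt(mean(cors6), 0.5)  # strong within-block LD when requested

  # sib and parent-offspring standardized relatedness center on 0.5
  ped2 <- simulate_pedigree(100, 2, seed = 4)
  g2 <- simulate_genotypes(ped2, 5000, 25, 0.6, c(0.05, 0.5), seed = 5)
  K <- grm_standardized(g2)$matrix
  fams <- sprintf("F%04d", 1:100)
  sib <- mean(K[cbind(paste0(fams, "_C1"), paste0(fams, "_C2"))])
  po <- mean(K[cbind(paste0(fams, "_P1"), paste0(fams, "_C1"))])
  expect_equal(sib, 0.5, tolerance = 0.05)
  expect_equal(po, 0.5, tolerance = 0.05)
})

test_that("point-normal effects match their architecture", {
  e0 <- simulate_effects(500, p_causal = 1, h2 = 0, seed = 1)
  expect_true(all(e0$beta == 0))

  e1 <- simulate_effects(10000, p_causal = 0.01, h2 = 0.5, seed = 2)
  k <- sum(e1$beta != 0)
  # binomial(10000, 0.01) central 99% interval
  expect_true(k >= qbinom(0.005, 10000, 0.01) &&
              k <= qbinom(0.995, 10000, 0.01))

  # genetic-value variance ~ h2 with standardized dosages
  ped <- simulate_pedigree(400, 1, seed = 3)
  g <- simulate_genotypes(ped, 2000, 20, 0.0, c(0.1, 0.5), seed = 4)
  eff <- simulate_effects(2000, 0.2, h2 = 0.4, seed = 5)
  Z <- scale(g$dosage)
  gv <- drop(Z %*% eff$beta)
  expect_equal(var(gv), 0.4, tolerance = 0.1)
})

test_that("exposures: family sharing, marginals, missingness knob", {
  ped <- simulate_pedigree(1000, 3, seed = 6)
  ex <- simulate_exposures(ped, n_visits = 3, seed = 7)
  expect_false(anyNA(ex$fiber))
  shared <- dplyr::summarize(dplyr::group_by(ex, family_id),
                             n_edu = dplyr::n_distinct(education),
                             n_reg = dplyr::n_distinct(region))
  expect_true(all(shared$n_edu == 1))  # education shared by sibs
  expect_true(all(shared$n_reg == 1))
  # fiber marginals follow the configured mean 8.17 / SD 1.31 within 3 SE
  n <- nrow(ex)
  expect_lt(abs(mean(ex$fiber) - 8.17), 3 * 1.31 / sqrt(n))
  expect_lt(abs(sd(ex$fiber) - 1.31), 3 * 1.31 / sqrt(2 * n))

  p <- default_exposure_params()
  p$mvpa$missing <- 0.3
  exm <- simulate_exposures(ped, p, n_visits = 2, seed = 8)
  expect_equal(mean(is.na(exm$mvpa)), 0.3, tolerance = 0.03)
  expect_false(anyNA(attr(exm, "complete")$mvpa))
})

test_that("phenotypes: null genotype effect, variance decomposition, counts", {
  ped <- simulate_pedigree(300, 2, seed = 9)
  g <- simulate_genotypes(ped, 500, 20, 0.5, c(0.1, 0.5), seed = 10)
  eff <- simulate_effects(500, 0.1, 0.4, seed = 11)
  ex <- simulate_exposures(ped, n_visits = 3, seed = 12)

  null_params <- default_effect_params()
  null_params$beta_prs <- 0
  null_params$beta_gxe <- lapply(null_params$beta_gxe, function(x) x * 0)
  sim0 <- simulate_phenotypes(g, eff, ex, sigma2_g = 0, sigma2_e = 1,
                              effect_params = null_params, seed = 13)
  S <- sim0$truth$prs_true[sim0$pheno$child_id]
  slope <- coef(lm(sim0$pheno$bmi_z ~ S))[2]
  expect_lt(abs(slope), 3 / sqrt(nrow(sim0$pheno)))  # ~3 SE of a null slope

  # flat fixed effects: var(y) = sigma2_g + sigma2_e
  flat <- null_params
  flat[c("intercept", "age", "sex", "fruit_veg", "fiber", "mvpa",
         "screen_time")] <- 0
  flat$region[] <- 0; flat$education[] <- 0
  sim1 <- simulate_phenotypes(g, eff, ex, sigma2_g = 0.4, sigma2_e = 0.6,
                              effect_params = flat, wc_params = flat, seed = 14)
  expect_equal(var(sim1$pheno$bmi_z), 1.0, tolerance = 0.1)
  expect_equal(nrow(sim1$pheno), 3 * 600)  # three visits, no attrition

  expect_equal(mean(sim1$pheno$obese), 0.07, tolerance = 0.005)
  ages <- tidyr::pivot_wider(sim1$pheno[, c("child_id", "visit", "age")],
                             names_from = "visit", values_from = "age")
  expect_equal(mean(ages$FU1 - ages$baseline), 2, tolerance = 0.1)
  expect_equal(mean(ages$FU2 - ages$baseline), 4, tolerance = 0.1)
  expect_true(all(ages$baseline >= 2 & ages$baseline <= 9.9))
})

test_that("whole-cohort generation is seed-deterministic", {
  a <- make_small_cohort(seed = 21)
  b <- make_small_cohort(seed = 21)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  c2 <- make_small_cohort(seed = 22)
  expect_false(identical(a$pheno$bmi_z, c2$pheno$bmi_z))
})

test_that("marginal GWAS betas track true effects", {
  ped <- simulate_pedigree(800, 1, seed = 30)
  g <- simulate_genotypes(ped, 1000, 20, 0.3, c(0.1, 0.5), seed = 31)
  founders <- subset_individuals(g, ped$individual_id[ped$role == "founder"])
  eff <- simulate_effects(1000, 0.1, 0.5, seed = 32)
  gw <- simulate_gwas(founders, eff, h2 = 0.5, seed = 33)
  expect_gt(cor(gw$beta, eff$beta), 0.3)
})
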