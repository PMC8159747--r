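test_that("BH step-up: hand cases and brute-force agreement", {
  expect_equal(bh_adjust(0.037), 0.037)  # m = 1: q = p
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # brute-force step-up oracle
  bh_brute <- function(p) {
    m <- length(p); ord <- order(p); q <- numeric(m)
    for (i in seq_len(m)) {
      q[ord[i]] <- min(1, min(p[ord][i:m] * m / (i:m)))
    }
    q
  }
  set.seed(3)
  for (r in 1:25) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_brute(p), tolerance = 1e-14)
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "prsgxe_invalid_argument")
})

test_that("AUC is the Mann-Whitney statistic with midrank ties", {
  expect_equal(auc(1:4, c(0, 0, 1, 1)), 1)
  expect_equal(auc(1:4, c(0, 1, 0, 1)), 0.75)
  expect_equal(auc(c(1, 1, 2, 2), c(0, 1, 0, 1)), 0.5)  # ties count half
  set.seed(4)
  expect_equal(auc(rnorm(2000), rbinom(2000, 1, 0.5)), 0.5, tolerance = 0.03)
  expect_error(auc(1:4, rep(1, 4)), class = "prsgxe_failure")
})

test_that("design builder: largest-n reference, centering, complete cases", {
  co <- make_small_cohort(n_families = 120, seed = 101)
  prs <- truth_prs(co)
  d <- build_design(co$pheno, prs, "bmi_z", exposure = "education")
  # the largest observed category is the (absent) reference level
  ref_edu <- names(which.max(table(co$pheno$education)))
  others <- setdiff(c("low", "medium", "high"), ref_edu)
  expect_true(all(paste0("education", others) %in% colnames(d$X)))
  expect_false(paste0("education", ref_edu) %in% colnames(d$X))
  ref_reg <- names(which.max(table(co$pheno$region)))
  expect_false(paste0("region", ref_reg) %in% colnames(d$X))
  # continuous exposures are centered and PRS standardized over children
  d2 <- build_design(co$pheno, prs, "bmi_z", exposure = "fiber")
  expect_lt(abs(mean(d2$X[, "fiber"])), 1e-10)
  kid <- !duplicated(d2$obs_individual)
  expect_lt(abs(mean(d2$X[kid, "prs"])), 1e-10)
  expect_lt(abs(sd(d2$X[kid, "prs"]) - 1), 1e-10)
  # no missing data: every observation is retained
  expect_equal(nrow(d2$X), nrow(co$pheno))
  # fiber models omit the fruit/veg covariate; others keep it
  expect_false("fruit_veg" %in% colnames(d2$X))
  expect_true("fruit_veg" %in% colnames(d$X))
  # listwise deletion drops exactly the incomplete rows for the model
  ph <- co$pheno
  ph$fiber[1:50] <- NA
  d3 <- build_design(ph, prs, "bmi_z", exposure = "fiber")
  expect_equal(nrow(d3$X), nrow(ph) - 50)
  d4 <- build_design(ph, prs, "bmi_z", exposure = "mvpa")  # fiber unused
  expect_equal(nrow(d4$X), nrow(ph))
  ph$bmi_z <- NA_real_
  expect_error(build_design(ph, prs, "bmi_z"), class = "prsgxe_failure")
})

test_that("main effects: shape, sign recovery, permutation null", {
  co <- make_small_cohort(n_families = 150, n_snps = 800, seed = 111)
  prs <- truth_prs(co)
  kin <- make_psd(grm_standardized(
    subset_individuals(co$genotypes, unique(co$pheno$child_id))))
  res <- main_effect_analysis(co$pheno, prs, kin,
                              plan = analysis_plan(outcomes = c("bmi_z", "obese")))
  expect_setequal(res$outcome, c("bmi_z", "obese"))
  expect_setequal(res$prs_scale, c("z", "top_decile"))
  cont <- res[res$outcome == "bmi_z" & res$prs_scale == "z", ]
  expect_gt(cont$estimate, 0.2)           # generator slope ~0.33/SD
  expect_lt(cont$p.value, 1e-6)
  expect_gt(cont$r2, 0.02)
  bin <- res[res$outcome == "obese" & res$prs_scale == "z", ]
  expect_gt(bin$estimate, 1)              # OR scale
  expect_gt(bin$auc, 0.55)
  # permuted PRS: slope and incremental r2 collapse
  set.seed(5)
  prs_perm <- dplyr::mutate(prs, z = sample(z), top_decile = sample(top_decile))
  resp <- main_effect_analysis(co$pheno, prs_perm, kin,
                               plan = analysis_plan(outcomes = "bmi_z"),
                               prs_scales = "z")
  expect_lt(abs(resp$estimate), 0.08)
  expect_lt(resp$r2, 0.01)
})

test_that("interaction analysis: contrasts, FDR family, q = p when m = 1", {
  co <- make_small_cohort(n_families = 100, seed = 121)
  prs <- truth_prs(co)
  kin <- make_psd(grm_standardized(
    subset_individuals(co$genotypes, unique(co$pheno$child_id))))
  plan <- analysis_plan(outcomes = "bmi_z",
                        exposures = c("fiber", "education"))
  res <- interaction_analysis(co$pheno, prs, kin, plan)
  expect_setequal(res$exposure, c("fiber", "education"))
  expect_equal(sum(res$exposure == "fiber"), 1)     # one product term
  expect_equal(sum(res$exposure == "education"), 2) # two contrasts
  expect_true(all(res$q.value >= res$p.value))
  expect_equal(res$q.value, bh_adjust(res$p.value))
  single <- interaction_analysis(co$pheno, prs, kin,
                                 analysis_plan(outcomes = "bmi_z",
                                               exposures = "fiber"))
  expect_equal(single$q.value, single$p.value)
})

test_that("stratified slopes: skipping, coherence with the interaction fit", {
  co <- make_small_cohort(n_families = 200, n_snps = 600, seed = 131)
  prs <- truth_prs(co)
  kin <- make_psd(grm_standardized(
    subset_individuals(co$genotypes, unique(co$pheno$child_id))))
  # small strata are skipped with a message
  plan_big <- analysis_plan(min_stratum_children = 10000)
  expect_message(
    s0 <- stratified_analysis(co$pheno, prs, kin, "bmi_z", "education",
                              plan_big),
    "skipped")
  expect_equal(nrow(s0), 0)
  expect_error(stratified_analysis(co$pheno, prs, kin, "bmi_z", "fiber"),
               class = "prsgxe_invalid_argument")

  # binary exposure: interaction estimate ~ difference of stratum slopes
  s <- stratified_analysis(co$pheno, prs, kin, "bmi_z", "sex",
                           analysis_plan(min_stratum_children = 20))
  expect_equal(nrow(s), 2)
  d <- build_design(co$pheno, prs, "bmi_z", exposure = "sex")
  fit <- fit_lmm(d$y, d$X, kin, d$obs_individual)
  w <- wald(fit, d$interaction_terms)
  # the contrast names the non-reference level; align the stratum difference
  lev <- if (grepl("sexM", w$term)) c("M", "F") else c("F", "M")
  diff_strat <- s$estimate[s$stratum == lev[1]] -
    s$estimate[s$stratum == lev[2]]
  se_strat <- sqrt(sum(((s$conf.high - s$conf.low) / (2 * 1.96))^2))
  expect_lt(abs(w$estimate - diff_strat), 2 * sqrt(w$se^2 + se_strat^2))
})

test_that("incremental r2: orthogonal PRS ~ 0, known share recovered", {
  set.seed(7)
  n <- 1500
  K <- diag(1e-12, n); rownames(K) <- colnames(K) <- paste0("i", 1:n)
  x <- rnorm(n); s <- rnorm(n)
  X <- cbind(intercept = 1, x = x, prs = s)
  # target share 0.11: var(b s) / (var(b s) + var(e)) with b chosen for it
  b <- sqrt(0.11 / 0.89)
  y <- 0.5 * x + b * s + rnorm(n)
  d <- list(y = y, X = X, prs_term = "prs", interaction_terms = character(0))
  fit <- fit_lmm(y, X, K)
  expect_equal(incremental_r2(fit, d), 0.11, tolerance = 0.025)
  # PRS unrelated to the outcome
  y0 <- 0.5 * x + rnorm(n)
  fit0 <- fit_lmm(y0, X, K)
  expect_lt(incremental_r2(fit0, list(y = y0, X = X, prs_term = "prs",
                                      interaction_terms = character(0))),
            0.01)
  expect_error(incremental_r2(fit, list(y = y, X = X, prs_term = "zz",
                                        interaction_terms = character(0))),
               class = "prsgxe_invalid_argument")
})
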