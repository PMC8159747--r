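make_geno <- function(dosage, ref, alt) {
  rownames(dosage) <- paste0("i", seq_len(nrow(dosage)))
  new_genotype_matrix <- getFromNamespace("new_genotype_matrix", "prsgxe")
  new_genotype_matrix(dosage, tibble::tibble(
    chrom = "1", pos = 100L * seq_along(ref), id = paste0("s", seq_along(ref)),
    ref = ref, alt = alt, maf_target = NA_real_
  ))
}

test_that("harmonization keeps, flips and drops by allele orientation", {
  g <- make_geno(matrix(c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 1L), 2),
                 ref = c("G", "G", "A", "C"), alt = c("A", "A", "T", "G"))
  w <- tibble::tibble(
    chrom = "1", pos = c(100L, 200L, 300L, 400L),
    effect_allele = c("A", "G", "A", "C"),
    other_allele = c("G", "A", "T", "A"),
    weight = c(0.5, 0.5, 0.5, 0.5)
  )
  out <- harmonize(w, g)
  audit <- attr(out, "audit")
  expect_equal(unname(audit["kept_as_is"]), 1)      # A/G vs ref G alt A
  expect_equal(unname(audit["flipped"]), 1)         # G/A vs ref G alt A
  expect_equal(unname(audit["palindromic_dropped"]), 1)  # A/T
  expect_equal(unname(audit["allele_mismatch"]), 1)      # C/A vs C/G
  expect_equal(out$weight, c(0.5, -0.5))
  # palindromic retained when strand is known
  out2 <- harmonize(w, g, drop_palindromic = FALSE)
  expect_equal(nrow(out2), 3)
  # zero overlap is a failure with diagnostics
  w_off <- dplyr::mutate(w, pos = pos + 7L)
  expect_error(harmonize(w_off, g), class = "prsgxe_failure")
})

test_that("scoring is the weighted dosage sum with mean imputation", {
  g <- make_geno(matrix(c(0L, 1L, 2L), 1), ref = c("A", "A", "A"),
                 alt = c("C", "C", "C"))
  mw <- tibble::tibble(col_index = 1:3, weight = c(0.1, -0.2, 0.3))
  expect_equal(score_prs(g, mw)$score, 0 * 0.1 - 0.2 + 2 * 0.3)
  expect_equal(score_prs(g, dplyr::mutate(mw, weight = 0))$score, 0)
  # missing dosage -> 2 * sample ALT frequency
  d <- matrix(c(0L, 2L, NA, 1L, 1L, 1L), 3)
  gm <- make_geno(d, ref = c("A", "A"), alt = c("C", "C"))
  s <- score_prs(gm, tibble::tibble(col_index = 1:2, weight = c(1, 0)))
  expect_equal(s$score[3], 2 * mean(c(0, 2)) / 2)
})

test_that("scores are invariant to allele-label orientation", {
  co <- make_small_cohort(seed = 41)
  founders <- subset_individuals(
    co$genotypes, co$pedigree$individual_id[co$pedigree$role == "founder"])
  gw <- simulate_gwas(founders, co$effects, seed = 42)
  a <- harmonize(gw, co$genotypes, drop_palindromic = FALSE)
  flipped <- dplyr::mutate(gw,
    tmp = effect_allele, effect_allele = other_allele,
    other_allele = tmp, weight = -weight, tmp = NULL)
  b <- harmonize(flipped, co$genotypes, drop_palindromic = FALSE)
  expect_lt(max(abs(score_prs(co$genotypes, a)$score -
                    score_prs(co$genotypes, b)$score)), 1e-10)
})

test_that("LDpred-inf closed forms and shrinkage", {
  beta <- c(0.3, -0.1, 0.05)
  # identity LD: elementwise shrink by 1 / (1 + M/(N h2))
  out <- ldpred_inf(beta, list(diag(3)), n_gwas = 1000, h2 = 0.5)
  expect_equal(out, beta / (1 + 3 / (1000 * 0.5)), tolerance = 1e-14)
  expect_lt(sqrt(sum(out^2)), sqrt(sum(beta^2)))  # strict shrinkage
  # vanishing ridge -> marginal betas back
  out0 <- ldpred_inf(beta, list(diag(3)), n_gwas = 1e12, h2 = 1)
  expect_equal(out0, beta, tolerance = 1e-9)
  # two-SNP block against the hand-inverted 2x2 system
  D <- matrix(c(1, 0.5, 0.5, 1), 2)
  b2 <- c(0.2, 0)
  # (D + I) beta_post = b2; inverse of [[2,.5],[.5,2]] is [[2,-.5],[-.5,2]]/3.75
  hand <- c(2 * 0.2 / 3.75, -0.5 * 0.2 / 3.75)
  expect_equal(ldpred_inf(b2, list(D), n_gwas = 2, h2 = 1), hand,
               tolerance = 1e-12)
  expect_error(ldpred_inf(beta, list(diag(3)), 1000, h2 = 0),
               class = "prsgxe_invalid_argument")
  expect_error(ldpred_inf(beta, list(diag(2)), 1000, h2 = 0.5),
               class = "prsgxe_invalid_argument")
})

test_that("clumping keeps the smaller-p member of correlated pairs", {
  set.seed(5)
  x1 <- rbinom(200, 2, 0.3)
  dosage <- cbind(x1, x1, rbinom(200, 2, 0.4))
  storage.mode(dosage) <- "integer"
  g <- make_geno(dosage, ref = rep("A", 3), alt = rep("C", 3))
  ms <- tibble::tibble(chrom = "1", pos = c(100L, 200L, 300L),
                       effect_allele = "C", other_allele = "A",
                       beta = c(0.2, 0.3, 0.1), p = c(1e-6, 1e-9, 1e-4))
  kept <- clump_threshold(ms, g, r2_max = 0.1, p_max = 1, block_size = 3)
  expect_equal(kept$pos, c(200L, 300L))  # r2 = 1 pair -> smaller p survives
  expect_equal(kept$weight, kept$beta)
  # p threshold below everything -> empty, with a message
  expect_message(none <- clump_threshold(ms, g, p_max = 1e-12, block_size = 3),
                 "no variant")
  expect_equal(nrow(none), 0)
  # independent SNPs all pass
  set.seed(6)
  d2 <- sapply(1:4, function(i) rbinom(500, 2, 0.4))
  storage.mode(d2) <- "integer"
  g2 <- make_geno(d2, ref = rep("A", 4), alt = rep("C", 4))
  ms2 <- tibble::tibble(chrom = "1", pos = c(100L, 200L, 300L, 400L),
                        effect_allele = "C", other_allele = "A",
                        beta = 0.1, p = c(0.01, 0.02, 0.03, 0.04))
  expect_equal(nrow(clump_threshold(ms2, g2, r2_max = 0.1, p_max = 0.05,
                                    block_size = 4)), 4)
})

test_that("genome-wide-significant filter", {
  ms <- tibble::tibble(p = c(1e-9, 4e-8, 6e-8, 0.5), beta = 1:4)
  expect_equal(gws_only(ms)$beta, 1:2)
  expect_equal(nrow(gws_only(dplyr::mutate(ms, p = p + 0.5))), 0)
  expect_equal(nrow(gws_only(ms, alpha = 1)), 4)
})

test_that("standardization: moments, top decile, degenerate input", {
  prs <- tibble::tibble(individual_id = sprintf("i%02d", 1:10),
                        score = c(5, 3, 8, 1, 9, 2, 7, 4, 6, 0))
  out <- standardize_prs(prs)
  expect_lt(abs(mean(out$z)), 1e-12)
  expect_lt(abs(sd(out$z) - 1), 1e-12)
  expect_equal(sum(out$top_decile), 1)
  expect_equal(out$individual_id[out$top_decile == 1], "i05")  # score 9
  expect_error(standardize_prs(dplyr::mutate(prs, score = 2)),
               class = "prsgxe_invalid_argument")
})

test_that("PRS accuracy grows with the GWAS panel size", {
  co <- make_small_cohort(n_families = 60, n_snps = 600, seed = 51)
  kids <- co$pedigree$individual_id[co$pedigree$role == "offspring"]
  cors <- sapply(c(200, 1600, 12800), function(n_panel) {
    panel_ped <- simulate_pedigree(n_panel / 2, 1, seed = n_panel)
    # same variant definitions as the scored cohort, fresh individuals
    panel <- simulate_genotypes(panel_ped, block_size = 20, ld_rho = 0.5,
                                seed = n_panel + 1,
                                variants = co$genotypes$variants)
    founders <- subset_individuals(
      panel, panel_ped$individual_id[panel_ped$role == "founder"])
    gw <- simulate_gwas(founders, co$effects, h2 = 0.5, seed = n_panel + 2)
    mw <- harmonize(gw, co$genotypes, drop_palindromic = FALSE)
    s <- score_prs(subset_individuals(co$genotypes, kids), mw)
    cor(s$score, co$truth$genetic_value[kids])
  })
  expect_true(all(diff(cors) > 0))
})
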