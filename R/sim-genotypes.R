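#' Simulate LD-blocked biallelic genotypes on a pedigree
#'
#' Founder haplotypes are drawn from a latent-Gaussian threshold model:
#' within each block of `block_size` adjacent SNPs the latent variables
#' follow an AR(1) process with correlation `ld_rho`, independent across
#' blocks, so within-block linkage disequilibrium is tunable while blocks
#' are independent. Offspring genotypes are produced by gene dropping: each
#' parent transmits, per block, one of its two haplotypes chosen at random
#' (recombination only at block boundaries). Dosages count the ALT allele.
#'
#' @param pedigree Pedigree tibble (see [simulate_pedigree()]).
#' @param n_snps Total number of SNPs (>= `block_size`).
#' @param block_size SNPs per LD block.
#' @param ld_rho Latent AR(1) correlation in `[0, 1)`.
#' @param maf_range Length-2 numeric, allele-frequency range in `(0, 0.5]`;
#'   each SNP's target MAF is drawn uniformly from it.
#' @param seed Integer seed.
#' @param variants Optional variant table from an existing
#'   `genotype_matrix`: the new cohort then carries the same variants
#'   (positions, alleles, target frequencies), so scores and summary
#'   statistics transfer between the two — e.g. an external GWAS panel for
#'   the cohort being analyzed.
#'
#' @return A `genotype_matrix` object: list with `dosage` (individuals x
#'   SNPs integer matrix, rownames = individual ids), and `variants` (tibble
#'   with `chrom`, `pos`, `id`, `ref`, `alt`, `maf_target`).
#' @export
simulate_genotypes <- function(pedigree, n_snps, block_size = 25L,
                               ld_rho = 0.6, maf_range = c(0.05, 0.5),
                               seed = 1L, variants = NULL) {
  validate_pedigree(pedigree)
  if (!is.null(variants)) n_snps <- nrow(variants)
  if (n_snps < 1 || block_size < 1 || n_snps < block_size) {
    stop_invalid("need n_snps >= block_size >= 1")
  }
  if (ld_rho < 0 || ld_rho >= 1) stop_invalid("ld_rho must be in [0, 1)")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop_invalid("maf_range must be (min, max) within (0, 0.5]")
  }
  n_snps <- as.integer(n_snps)
  block_size <- as.integer(block_size)
  set.seed(seed)

  founders <- pedigree$individual_id[pedigree$role == "founder"]
  offspring <- pedigree[pedigree$role == "offspring", ]
  n_f <- length(founders)
  maf <- if (is.null(variants)) runif(n_snps, maf_range[1], maf_range[2]) else
    variants$maf_target
  thr <- qnorm(maf)

  block_id <- rep(seq_len(ceiling(n_snps / block_size)), each = block_size)[seq_len(n_snps)]
  n_blocks <- max(block_id)

  # founder haplotypes: 2 per founder, rows = haplotypes
  n_hap <- 2L * n_f
  hap <- matrix(0L, n_hap, n_snps)
  for (b in seq_len(n_blocks)) {
    cols <- which(block_id == b)
    k <- length(cols)
    z <- matrix(rnorm(n_hap * k), n_hap, k)
    if (ld_rho > 0 && k > 1) {
      for (j in 2:k) z[, j] <- ld_rho * z[, j - 1] + sqrt(1 - ld_rho^2) * z[, j]
    }
    hap[, cols] <- 1L * (z < rep(thr[cols], each = n_hap))
  }
  # haplotype rows 2i-1, 2i belong to founder i
  f_index <- stats::setNames(seq_len(n_f), founders)

  ids <- pedigree$individual_id
  dosage <- matrix(0L, length(ids), n_snps, dimnames = list(ids, NULL))
  dosage[founders, ] <- hap[2L * f_index - 1L, , drop = FALSE] +
    hap[2L * f_index, , drop = FALSE]

  # gene dropping: per offspring, per parent, choose a haplotype per block
  if (nrow(offspring) > 0) {
    for (parent_col in c("father_id", "mother_id")) {
      p_idx <- f_index[offspring[[parent_col]]]
      pick <- matrix(stats::rbinom(nrow(offspring) * n_blocks, 1L, 0.5),
                     nrow(offspring), n_blocks)
      hap_row <- 2L * p_idx - 1L + pick          # n_off x n_blocks haplotype rows
      tr <- matrix(0L, nrow(offspring), n_snps)
      for (b in seq_len(n_blocks)) {
        cols <- which(block_id == b)
        tr[, cols] <- hap[hap_row[, b], cols, drop = FALSE]
      }
      dosage[offspring$individual_id, ] <- dosage[offspring$individual_id, , drop = FALSE] + tr
    }
  }

  if (is.null(variants)) {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_snps, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
    variants <- tibble::tibble(
      chrom = as.character(block_id %% 22L + 1L),
      pos = 1000L * seq_len(n_snps),
      id = sprintf("snp%05d", seq_len(n_snps)),
      ref = ref, alt = unname(alt), maf_target = maf
    )
  }
  new_genotype_matrix(dosage, variants)
}

new_genotype_matrix <- function(dosage, variants) {
  stopifnot(ncol(dosage) == nrow(variants), !is.null(rownames(dosage)))
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d variants\n",
              nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

#' Subset a genotype matrix by individual id
#'
#' @param geno A `genotype_matrix`.
#' @param ids Individual ids to keep, in the requested order.
#' @return A `genotype_matrix` restricted to `ids`.
#' @export
subset_individuals <- function(geno, ids) {
  stopifnot(inherits(geno, "genotype_matrix"))
  missing_ids <- setdiff(ids, rownames(geno$dosage))
  if (length(missing_ids)) {
    stop_invalid(paste("unknown individual ids:", paste(head(missing_ids, 5), collapse = ", ")))
  }
  new_genotype_matrix(geno$dosage[ids, , drop = FALSE], geno$variants)
}

# column-standardize dosages by sample allele frequency; monomorphic -> 0.
# Missing dosages are mean-imputed (2f) before standardization.
standardize_dosage <- function(dosage) {
  f <- colMeans(dosage, na.rm = TRUE) / 2
  if (anyNA(dosage)) {
    imp <- rep(2 * f, each = nrow(dosage))
    dosage[is.na(dosage)] <- imp[is.na(dosage)]
  }
  denom <- sqrt(2 * f * (1 - f))
  Z <- sweep(dosage, 2, 2 * f, "-")
  keep <- denom > 0
  Z[, keep] <- sweep(Z[, keep, drop = FALSE], 2, denom[keep], "/")
  Z[, !keep] <- 0
  Z
}
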