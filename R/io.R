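#' Read genotype dosages from a VCF
#'
#' Reads biallelic SNP records (others are skipped and counted) from a VCF
#' via `vcfR`, converts GT fields to ALT-allele dosages, and applies MAF
#' and per-variant missingness filters. Positions are 1-based throughout.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param maf_min Minimum minor-allele frequency (default 0).
#' @param missing_max Maximum per-variant missing fraction (default 1).
#' @return A `genotype_matrix`; the `"filter_log"` attribute counts skipped
#'   and filtered records.
#' @export
read_genotypes <- function(path, maf_min = 0, missing_max = 1) {
  if (!file.exists(path)) stop_failure(paste("VCF not found:", path))
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop_failure(paste("unreadable VCF:",
                                                         conditionMessage(e))))
  fx <- vcfR::getFIX(vcf)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  biallelic <- !grepl(",", fx[, "ALT"]) & nchar(fx[, "REF"]) == 1 &
    nchar(fx[, "ALT"]) == 1 & fx[, "ALT"] != "."
  n_skipped <- sum(!biallelic)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fx <- fx[biallelic, , drop = FALSE]
  # count ALT alleles in the GT string; "." -> NA
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean == "0/0"] <- 0L
  dos[clean == "0/1" | clean == "1/0"] <- 1L
  dos[clean == "1/1"] <- 2L
  X <- t(dos)
  rownames(X) <- colnames(gt)

  miss_frac <- colMeans(is.na(X))
  f <- colMeans(X, na.rm = TRUE) / 2
  f[is.nan(f)] <- 0
  maf <- pmin(f, 1 - f)
  keep <- miss_frac <= missing_max & maf >= maf_min
  filter_log <- c(records = length(biallelic), multi_or_nonsnp = n_skipped,
                  failed_missingness = sum(miss_frac > missing_max),
                  failed_maf = sum(maf < maf_min & miss_frac <= missing_max),
                  retained = sum(keep))
  if (!any(keep)) stop_failure("no variant passed the VCF filters")
  variants <- tibble::tibble(
    chrom = fx[keep, "CHROM"], pos = as.integer(fx[keep, "POS"]),
    id = ifelse(is.na(fx[keep, "ID"]), ".", fx[keep, "ID"]),
    ref = fx[keep, "REF"], alt = fx[keep, "ALT"],
    maf_target = maf[keep]
  )
  out <- new_genotype_matrix(X[, keep, drop = FALSE], variants)
  attr(out, "filter_log") <- filter_log
  out
}

#' Write a genotype matrix as VCF
#'
#' Emits a minimal VCF v4.2 with GT fields (unphased diploid genotypes
#' reconstructed from dosages; dosage 1 is written `0/1`).
#'
#' @param genotypes A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  v <- genotypes$variants
  X <- genotypes$dosage
  gt_map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", ncol(X), nrow(X))
  known <- !is.na(t(X))
  gt[known] <- gt_map[as.character(t(X)[known])]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=prsgxe-simulator",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(X)), collapse = "\t")
  )
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write a PRS weight table (TSV)
#'
#' Columns: `chrom`, `pos`, `effect_allele`, `other_allele`, `weight`, and
#' optionally `beta`, `se`, `p`, `n`.
#'
#' @param path TSV path.
#' @return A validated weight-table tibble.
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) stop_failure(paste("weight table not found:", path))
  w <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(chrom = "c", .default = "?"))
  req <- c("chrom", "pos", "effect_allele", "other_allele", "weight")
  if (!all(req %in% names(w))) {
    stop_failure(paste("weight table needs columns:", paste(req, collapse = ", ")))
  }
  if (any(!w$effect_allele %in% c("A", "C", "G", "T")) ||
      any(!w$other_allele %in% c("A", "C", "G", "T"))) {
    stop_failure("alleles must be A/C/G/T")
  }
  if (any(!is.finite(w$weight))) stop_failure("weights must be finite")
  if (anyDuplicated(paste(w$chrom, w$pos, w$effect_allele, w$other_allele))) {
    stop_failure("duplicate (chrom, pos, alleles) rows in weight table")
  }
  w
}

#' @rdname read_weights
#' @param weights Weight-table tibble.
#' @export
write_weights <- function(weights, path) {
  readr::write_tsv(weights, path)
  invisible(path)
}

#' Read a phenotype table (CSV, one row per child-visit)
#'
#' Validates the closed vocabularies (`visit`, `sex`, `region`,
#' `education`), normalizes empty cells to missing, and logs row count and
#' per-column missingness.
#'
#' @param path CSV path.
#' @return Phenotype tibble; missingness counts in the `"missing_log"`
#'   attribute.
#' @export
read_pheno <- function(path) {
  if (!file.exists(path)) stop_failure(paste("phenotype table not found:", path))
  ph <- readr::read_csv(path, show_col_types = FALSE,
                        na = c("", "NA"))
  req <- c("child_id", "visit", "age", "sex")
  if (!all(req %in% names(ph))) {
    stop_failure(paste("phenotype table needs columns:", paste(req, collapse = ", ")))
  }
  vocab <- list(visit = c("baseline", "FU1", "FU2"), sex = c("M", "F"),
                region = c("Central", "North", "South"),
                education = c("low", "medium", "high"))
  for (v in intersect(names(vocab), names(ph))) {
    bad <- which(!is.na(ph[[v]]) & !ph[[v]] %in% vocab[[v]])
    if (length(bad)) {
      stop_failure(sprintf("unknown %s value '%s' in row %d",
                           v, ph[[v]][bad[1]], bad[1]))
    }
  }
  if (anyDuplicated(paste(ph$child_id, ph$visit))) {
    stop_failure("duplicate child-visit rows")
  }
  for (v in intersect(c("region", "education"), names(ph))) {
    ph[[v]] <- factor(ph[[v]], levels = vocab[[v]])
  }
  miss <- vapply(ph, function(x) sum(is.na(x)), integer(1))
  inform(sprintf("read %d child-visit rows; columns with missing values: %s",
                 nrow(ph),
                 if (any(miss > 0)) {
                   paste(names(miss)[miss > 0], miss[miss > 0],
                         sep = "=", collapse = ", ")
                 } else "none"))
  attr(ph, "missing_log") <- miss
  ph
}

#' @rdname read_pheno
#' @param pheno Phenotype tibble.
#' @export
write_pheno <- function(pheno, path) {
  readr::write_csv(pheno, path)
  invisible(path)
}

#' Run the full PRS / GRM / main-effect / interaction / stratified pipeline
#'
#' Given file paths (or in-memory objects), executes: genotype ingestion,
#' weight harmonization and scoring, PRS standardization, GRM construction,
#' main-effect analysis, interaction analysis with FDR, and stratified
#' slopes for the categorical exposures. Writes tidy TSV/JSON results plus
#' a run manifest (configuration echo, seed, package version, input
#' checksums) when `output_dir` is given. Fully deterministic given the
#' config.
#'
#' @param genotypes `genotype_matrix` or VCF path.
#' @param weights Weight-table tibble or TSV path.
#' @param pheno Phenotype tibble or CSV path.
#' @param output_dir Optional directory for result files.
#' @param plan An [analysis_plan()].
#' @param maf_min MAF filter for the GRM.
#' @param drop_palindromic Passed to [harmonize()].
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return List: `prs`, `kinship` (not written unless `output_dir`),
#'   `main_effects`, `interactions`, `strata`, `manifest`.
#' @export
run_pipeline <- function(genotypes, weights, pheno, output_dir = NULL,
                         plan = analysis_plan(), maf_min = 0.01,
                         drop_palindromic = TRUE, seed = 1L) {
  if (is.character(genotypes)) genotypes <- read_genotypes(genotypes)
  if (is.character(weights)) weights <- read_weights(weights)
  if (is.character(pheno)) pheno <- read_pheno(pheno)
  children <- unique(pheno$child_id)
  missing_kids <- setdiff(children, rownames(genotypes$dosage))
  if (length(missing_kids)) {
    stop_failure(paste("children without genotypes:",
                       paste(head(missing_kids, 5), collapse = ", ")))
  }
  geno_kids <- subset_individuals(genotypes, children)

  matched <- harmonize(weights, geno_kids, drop_palindromic = drop_palindromic)
  prs <- standardize_prs(score_prs(geno_kids, matched))
  kin <- make_psd(grm_standardized(geno_kids, maf_min = maf_min))

  main <- main_effect_analysis(pheno, prs, kin, plan)
  inter <- interaction_analysis(pheno, prs, kin, plan)
  cont <- plan$outcomes[plan$outcome_type == "continuous"]
  strata <- purrr::map_dfr(
    intersect(plan$exposures, plan$categorical),
    function(ex) purrr::map_dfr(cont, function(oc) {
      dplyr::mutate(
        tibble::as_tibble(stratified_analysis(pheno, prs, kin, oc, ex, plan)),
        outcome = oc, exposure = ex, .before = 1)
    })
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("prsgxe")),
    seed = seed,
    n_children = length(children), n_obs = nrow(pheno),
    n_variants = ncol(geno_kids$dosage),
    harmonization = as.list(attr(matched, "audit")),
    plan = unclass(plan)
  )
  out <- list(prs = prs, kinship = kin, main_effects = main,
              interactions = inter, strata = strata, manifest = manifest)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(main, file.path(output_dir, "main_effects.tsv"))
    readr::write_tsv(inter, file.path(output_dir, "interactions.tsv"))
    readr::write_tsv(strata, file.path(output_dir, "stratified_slopes.tsv"))
    readr::write_csv(prs, file.path(output_dir, "prs.csv"))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}
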