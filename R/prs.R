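#' Harmonize a weight table to the genotype allele orientation
#'
#' Dosages count the ALT allele, so each weight must be expressed per ALT
#' copy: where the weight's (effect, other) alleles equal (alt, ref) the
#' weight is kept; where they equal (ref, alt) it is negated; palindromic
#' (A/T, C/G) pairs are strand-ambiguous and dropped by default; variants
#' whose allele pairs do not match are dropped. Matching is keyed on
#' `(chrom, pos)`.
#'
#' @param weights Weight table: `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `weight` (optionally `beta`, `se`, `p`, `n`).
#' @param genotypes A `genotype_matrix`.
#' @param drop_palindromic Drop A/T and C/G pairs (default TRUE; can be
#'   disabled for simulated data of known strand).
#' @return The matched weight table (one row per scored variant, with
#'   `col_index` into the dosage matrix), with an `audit` attribute counting
#'   variants kept / flipped / dropped by reason.
#' @export
harmonize <- function(weights, genotypes, drop_palindromic = TRUE) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  req <- c("chrom", "pos", "effect_allele", "other_allele", "weight")
  if (!all(req %in% names(weights))) {
    stop_invalid(paste("weight table needs columns:", paste(req, collapse = ", ")))
  }
  v <- genotypes$variants
  key_g <- paste(v$chrom, v$pos)
  key_w <- paste(weights$chrom, weights$pos)
  idx <- match(key_w, key_g)
  present <- !is.na(idx)
  w <- weights[present, , drop = FALSE]
  gi <- idx[present]

  pal <- function(a, b) paste0(a, b) %in% c("AT", "TA", "CG", "GC")
  is_pal <- pal(w$effect_allele, w$other_allele)
  same <- w$effect_allele == v$alt[gi] & w$other_allele == v$ref[gi]
  flip <- w$effect_allele == v$ref[gi] & w$other_allele == v$alt[gi]
  drop_pal <- drop_palindromic & is_pal
  keep <- (same | flip) & !drop_pal

  audit <- c(
    input = nrow(weights),
    no_position_match = sum(!present),
    palindromic_dropped = sum(drop_pal & (same | flip)),
    allele_mismatch = sum(!(same | flip)),
    kept_as_is = sum(same & keep),
    flipped = sum(flip & keep)
  )
  if (!any(keep)) {
    stop_failure(paste0(
      "no variant could be harmonized (",
      paste(names(audit), audit, sep = "=", collapse = ", "), ")"))
  }
  out <- w[keep, , drop = FALSE]
  out$weight <- ifelse(flip[keep], -out$weight, out$weight)
  out$col_index <- gi[keep]
  out <- tibble::as_tibble(out)
  attr(out, "audit") <- audit
  out
}

#' Dosage-weighted polygenic score
#'
#' `score_i = sum_j w_j dosage_ij` over the harmonized variants; missing
#' dosages are mean-imputed at `2 * (sample ALT frequency)`.
#'
#' @param genotypes A `genotype_matrix`.
#' @param matched_weights Output of [harmonize()] (needs `col_index`,
#'   `weight`).
#' @return Tibble: `individual_id`, `score`.
#' @export
score_prs <- function(genotypes, matched_weights) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!"col_index" %in% names(matched_weights)) {
    stop_invalid("weights must be harmonized first (missing col_index)")
  }
  X <- genotypes$dosage[, matched_weights$col_index, drop = FALSE]
  if (anyNA(X)) {
    f <- colMeans(X, na.rm = TRUE) / 2
    imp <- rep(2 * f, each = nrow(X))
    X[is.na(X)] <- imp[is.na(X)]
  }
  tibble::tibble(
    individual_id = rownames(genotypes$dosage),
    score = unname(drop(X %*% matched_weights$weight))
  )
}

#' LDpred infinitesimal posterior-mean reweighting
#'
#' Under the infinitesimal model the posterior mean effects given marginal
#' GWAS estimates have the closed form, per LD block,
#' `beta_post = (D + (M / (N h2)) I)^{-1} beta_marginal`, with `D` the block
#' LD (correlation) matrix, `M` the total number of scored variants, `N`
#' the GWAS sample size and `h2` the trait heritability. The ridge term is
#' strictly positive, so the solve always exists. (The point-normal prior
#' variant with a Gibbs sampler is out of scope; the sparsity notion
#' survives in the simulator's causal architecture.)
#'
#' @param marginal_betas Numeric vector of marginal effects (all blocks,
#'   concatenated in order).
#' @param ld_blocks List of symmetric PSD LD matrices whose sizes sum to
#'   `length(marginal_betas)`.
#' @param n_gwas GWAS sample size (> 0).
#' @param h2 Heritability in `(0, 1]`.
#' @return Numeric vector of reweighted effects, same order.
#' @export
ldpred_inf <- function(marginal_betas, ld_blocks, n_gwas, h2) {
  if (h2 <= 0 || h2 > 1) stop_invalid("h2 must be in (0, 1]")
  if (n_gwas <= 0) stop_invalid("n_gwas must be positive")
  sizes <- vapply(ld_blocks, nrow, integer(1))
  if (sum(sizes) != length(marginal_betas)) {
    stop_invalid("LD block sizes must sum to the number of variants")
  }
  M <- length(marginal_betas)
  ridge <- M / (n_gwas * h2)
  out <- numeric(M)
  start <- 1L
  for (D in ld_blocks) {
    k <- nrow(D)
    sel <- start:(start + k - 1L)
    out[sel] <- solve(D + diag(ridge, k), marginal_betas[sel])
    start <- start + k
  }
  out
}

#' Empirical LD (dosage correlation) matrices per block
#'
#' @param genotypes A `genotype_matrix`.
#' @param block_size Adjacent-SNP block size.
#' @return List of correlation matrices (monomorphic SNPs get unit diagonal,
#'   zero off-diagonal).
#' @export
ld_blocks_empirical <- function(genotypes, block_size) {
  X <- genotypes$dosage
  m <- ncol(X)
  block_id <- rep(seq_len(ceiling(m / block_size)), each = block_size)[seq_len(m)]
  lapply(split(seq_len(m), block_id), function(cols) {
    D <- suppressWarnings(stats::cor(X[, cols, drop = FALSE]))
    D[!is.finite(D)] <- 0
    diag(D) <- 1
    (D + t(D)) / 2
  })
}

#' Greedy clumping and thresholding (PRSice-style)
#'
#' Variants are sorted by ascending p value; a variant is kept iff its p
#' value is at most `p_max` and its squared dosage correlation with every
#' already-kept variant inside the window (same LD block by default, or a
#' base-pair window) is at most `r2_max`. Weights of the kept variants are
#' their marginal betas.
#'
#' @param marginal_stats Weight-table tibble with `p` and `beta` columns,
#'   rows aligned to the genotype variants via `chrom`/`pos`.
#' @param genotypes A `genotype_matrix`.
#' @param r2_max Maximum allowed r^2 with kept variants (default 0.1).
#' @param p_max P-value threshold (default 1).
#' @param window Either `"block"` (default; the simulator's LD blocks,
#'   inferred from `block_size`) or a window half-width in base pairs.
#' @param block_size Block size when `window = "block"`.
#' @return Subset of `marginal_stats` with `weight = beta`, plus
#'   `col_index`.
#' @export
clump_threshold <- function(marginal_stats, genotypes, r2_max = 0.1,
                            p_max = 1, window = "block", block_size = 25L) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!all(c("p", "beta") %in% names(marginal_stats))) {
    stop_invalid("marginal stats need p and beta columns")
  }
  v <- genotypes$variants
  idx <- match(paste(marginal_stats$chrom, marginal_stats$pos),
               paste(v$chrom, v$pos))
  if (anyNA(idx)) stop_invalid("marginal stats contain variants absent from the genotypes")
  stats_ord <- order(marginal_stats$p)
  stats_ord <- stats_ord[marginal_stats$p[stats_ord] <= p_max]
  if (length(stats_ord) == 0) {
    inform("clumping retained no variant (p threshold below all p values)")
    out <- marginal_stats[0, ]
    out$col_index <- integer(0)
    return(tibble::as_tibble(out))
  }
  m <- ncol(genotypes$dosage)
  if (identical(window, "block")) {
    win_id <- rep(seq_len(ceiling(m / block_size)),
                  each = block_size)[seq_len(m)]
    in_window <- function(a, b) win_id[a] == win_id[b]
  } else {
    in_window <- function(a, b) v$chrom[a] == v$chrom[b] &
      abs(v$pos[a] - v$pos[b]) <= window
  }
  X <- genotypes$dosage
  kept <- integer(0)
  for (j in stats_ord) {
    cj <- idx[j]
    near <- kept[in_window(idx[kept], rep(cj, length(kept)))]
    ok <- TRUE
    for (k in near) {
      r <- suppressWarnings(stats::cor(X[, cj], X[, idx[k]]))
      if (is.finite(r) && r^2 > r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, j)
  }
  out <- marginal_stats[sort(kept), , drop = FALSE]
  out$weight <- out$beta
  out$col_index <- idx[sort(kept)]
  tibble::as_tibble(out)
}

#' Genome-wide-significant subset
#'
#' @param marginal_stats Weight table with a `p` column.
#' @param alpha Significance threshold (default 5e-8).
#' @return Rows with `p <= alpha`, `weight = beta`.
#' @export
gws_only <- function(marginal_stats, alpha = 5e-8) {
  if (!"p" %in% names(marginal_stats)) stop_invalid("marginal stats need a p column")
  out <- marginal_stats[marginal_stats$p <= alpha, , drop = FALSE]
  if ("beta" %in% names(out)) out$weight <- out$beta
  tibble::as_tibble(out)
}

#' Standardize a polygenic score over the analysis sample
#'
#' Returns the sample z-score and a top-decile indicator (highest 10% by
#' score; ties broken by individual id order, computed on the analysis
#' sample rather than an external reference).
#'
#' @param prs Tibble with `individual_id` and `score` (from [score_prs()]).
#' @return Tibble: `individual_id`, `score`, `z`, `top_decile`.
#' @export
standardize_prs <- function(prs) {
  if (is.data.frame(prs)) {
    if (!all(c("individual_id", "score") %in% names(prs))) {
      stop_invalid("prs must have individual_id and score columns")
    }
    ids <- prs$individual_id
    raw <- prs$score
  } else {
    raw <- prs
    ids <- names(prs) %||% as.character(seq_along(prs))
  }
  s <- sd(raw)
  if (!is.finite(s) || s == 0) stop_invalid("scores have zero variance; cannot standardize")
  n <- length(raw)
  n_top <- floor(n / 10)
  ord <- order(-raw, ids)  # highest scores first, id order breaks ties
  top <- integer(n)
  if (n_top > 0) top[ord[seq_len(n_top)]] <- 1L
  tibble::tibble(
    individual_id = ids, score = raw,
    z = (raw - mean(raw)) / s, top_decile = top
  )
}
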