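#' Genetic relatedness matrices
#'
#' `grm_standardized()` computes the standardized (GCTA/Balding-Nichols
#' style) relatedness matrix `V = Z Z' / M` over the `M` variants passing
#' the MAF filter, with `Z` the column-standardized dosage matrix
#' `(x - 2f) / sqrt(2 f (1 - f))` at sample allele frequency `f` (missing
#' dosages mean-imputed first). `grm_ibs()` computes identity-by-state
#' kinship `V_ij = mean(1 - |x_i - x_j| / 2)`. Either can structure the
#' random intercept of the mixed models; the standardized form is the
#' default because its variance component has a direct heritability-style
#' interpretation.
#'
#' @param genotypes A `genotype_matrix`.
#' @param maf_min Minor-allele-frequency filter applied before the
#'   standardized GRM (default 0.01).
#' @return A `kinship` object: list with `ids` (ordered individual ids) and
#'   `matrix` (dense symmetric matrix with dimnames).
#' @export
grm_standardized <- function(genotypes, maf_min = 0.01) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  X <- genotypes$dosage
  if (nrow(X) < 2) stop_invalid("need at least 2 individuals for a GRM")
  f <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  keep <- maf >= maf_min & maf > 0
  if (!any(keep)) stop_failure("no variant passes the MAF filter")
  Z <- standardize_dosage(X[, keep, drop = FALSE])
  V <- tcrossprod(Z) / sum(keep)
  V <- (V + t(V)) / 2
  dimnames(V) <- list(rownames(X), rownames(X))
  new_kinship(V)
}

#' @rdname grm_standardized
#' @export
grm_ibs <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  X <- genotypes$dosage
  if (nrow(X) < 2) stop_invalid("need at least 2 individuals for a GRM")
  if (anyNA(X)) {
    f <- colMeans(X, na.rm = TRUE) / 2
    imp <- rep(2 * f, each = nrow(X))
    X[is.na(X)] <- imp[is.na(X)]
  }
  M <- ncol(X)
  # mean(1 - |xi - xj|/2) = 1 - (sum xi^2 + sum xj^2 - 2 xi.xj) ... |.| is not
  # squared, so expand over the three dosage levels instead: |a-b| for
  # a,b in {0,1,2}. Use indicator matrices per level.
  I0 <- (X == 0) + 0; I1 <- (X == 1) + 0; I2 <- (X == 2) + 0
  # |a-b|: 0 same level; 1 adjacent; 2 opposite homozygotes
  D <- tcrossprod(I0, I1) + tcrossprod(I1, I0) +
    tcrossprod(I1, I2) + tcrossprod(I2, I1) +
    2 * (tcrossprod(I0, I2) + tcrossprod(I2, I0))
  V <- 1 - D / (2 * M)
  V <- (V + t(V)) / 2
  dimnames(V) <- list(rownames(X), rownames(X))
  new_kinship(V)
}

new_kinship <- function(V) {
  stopifnot(is.matrix(V), nrow(V) == ncol(V), !is.null(rownames(V)))
  structure(list(ids = rownames(V), matrix = V), class = "kinship")
}

#' @export
print.kinship <- function(x, ...) {
  cat(sprintf("<kinship> %d individuals; mean diagonal %.3f\n",
              length(x$ids), mean(diag(x$matrix))))
  invisible(x)
}

#' Project a kinship matrix onto the positive semidefinite cone
#'
#' Eigenvalues below `eps` are clamped to `eps` and the matrix is
#' reconstructed; the largest absolute entry-wise adjustment is recorded in
#' the `"max_adjustment"` attribute. Estimated GRMs can be indefinite after
#' filtering/imputation; the mixed models require PSD covariance.
#'
#' @param kinship A `kinship` object (or bare symmetric matrix).
#' @param eps Eigenvalue floor.
#' @return A PSD `kinship` object.
#' @export
make_psd <- function(kinship, eps = 1e-8) {
  V <- if (inherits(kinship, "kinship")) kinship$matrix else kinship
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE)
  if (min(ev$values) >= eps) {
    out <- new_kinship(V)
    attr(out, "max_adjustment") <- 0
    attr(out, "eigen") <- list(values = ev$values, vectors = ev$vectors)
    return(out)
  }
  lam <- pmax(ev$values, eps)
  V2 <- ev$vectors %*% (lam * t(ev$vectors))
  V2 <- (V2 + t(V2)) / 2
  dimnames(V2) <- dimnames(V)
  out <- new_kinship(V2)
  attr(out, "max_adjustment") <- max(abs(V2 - V))
  # eigensystem of the repaired matrix, reusable by downstream consumers
  attr(out, "eigen") <- list(values = lam, vectors = ev$vectors)
  out
}

#' Expand individual-level kinship to observation level
#'
#' With repeated visits, the random intercept is shared across one child's
#' observations, so the observation-level covariance is `Z V Z'` with `Z`
#' the 0/1 incidence matrix mapping observations to individuals.
#'
#' @param kinship A `kinship` object.
#' @param obs_individual Character vector, one entry per observation, giving
#'   the individual each observation belongs to.
#' @return Dense observation-level covariance matrix.
#' @export
expand_to_observations <- function(kinship, obs_individual) {
  stopifnot(inherits(kinship, "kinship"))
  miss <- setdiff(unique(obs_individual), kinship$ids)
  if (length(miss)) {
    stop_invalid(paste("observations refer to individuals absent from the kinship:",
                       paste(head(miss, 5), collapse = ", ")))
  }
  idx <- match(obs_individual, kinship$ids)
  S <- kinship$matrix[idx, idx, drop = FALSE]
  dimnames(S) <- list(obs_individual, obs_individual)
  S
}

#' Write / read a kinship matrix
#'
#' `format = "matrix"` writes an ids file (one id per line, `<path>.ids`)
#' plus a dense whitespace-delimited matrix; `format = "long"` writes a
#' single `(i, j, value)` TSV of the upper triangle including the diagonal.
#'
#' @param kinship A `kinship` object.
#' @param path Output path (matrix file for `"matrix"`, TSV for `"long"`).
#' @param format `"matrix"` or `"long"`.
#' @return `write_kinship()` returns `path` invisibly; `read_kinship()` a
#'   `kinship` object.
#' @export
write_kinship <- function(kinship, path, format = c("matrix", "long")) {
  stopifnot(inherits(kinship, "kinship"))
  format <- match.arg(format)
  if (format == "matrix") {
    writeLines(kinship$ids, paste0(path, ".ids"))
    utils::write.table(kinship$matrix, path, row.names = FALSE,
                       col.names = FALSE)
  } else {
    ut <- which(upper.tri(kinship$matrix, diag = TRUE), arr.ind = TRUE)
    readr::write_tsv(tibble::tibble(
      i = kinship$ids[ut[, 1]], j = kinship$ids[ut[, 2]],
      value = kinship$matrix[ut]
    ), path)
  }
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path, format = c("matrix", "long")) {
  format <- match.arg(format)
  if (format == "matrix") {
    ids <- readLines(paste0(path, ".ids"))
    V <- as.matrix(utils::read.table(path))
    dimnames(V) <- list(ids, ids)
  } else {
    long <- readr::read_tsv(path, col_types = "ccd", show_col_types = FALSE)
    ids <- unique(c(long$i, long$j))
    V <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    V[cbind(long$i, long$j)] <- long$value
    V[cbind(long$j, long$i)] <- long$value
  }
  new_kinship(V)
}
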