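#' Simulate a nuclear-family pedigree
#'
#' Builds a cohort of unrelated nuclear families, each with two founder
#' parents and a fixed number of offspring. Offspring sex is assigned
#' Bernoulli(0.5). This is the relatedness backbone used by the genotype
#' simulator (gene dropping) and by the kinship-aware mixed models.
#'
#' @param n_families Number of families (>= 1).
#' @param offspring_per_family Offspring per family (>= 1).
#' @param seed Integer seed; the pedigree is fully determined by it.
#'
#' @return A tibble with columns `individual_id`, `family_id`, `father_id`,
#'   `mother_id` (both `NA` for founders), `sex` (`"M"`/`"F"`) and `role`
#'   (`"founder"`/`"offspring"`).
#' @export
#' @examples
#' simulate_pedigree(2, 2, seed = 1)
simulate_pedigree <- function(n_families, offspring_per_family, seed = 1L) {
  if (!is.numeric(n_families) || n_families < 1 ||
      !is.numeric(offspring_per_family) || offspring_per_family < 1) {
    stop_invalid("`n_families` and `offspring_per_family` must be >= 1")
  }
  n_families <- as.integer(n_families)
  offspring_per_family <- as.integer(offspring_per_family)
  set.seed(seed)
  fam <- sprintf("F%04d", seq_len(n_families))
  founders <- tibble::tibble(
    individual_id = c(paste0(fam, "_P1"), paste0(fam, "_P2")),
    family_id = rep(fam, 2L),
    father_id = NA_character_,
    mother_id = NA_character_,
    sex = rep(c("M", "F"), each = n_families),
    role = "founder"
  )
  kids <- tidyr::expand_grid(family_id = fam, k = seq_len(offspring_per_family))
  offspring <- tibble::tibble(
    individual_id = sprintf("%s_C%d", kids$family_id, kids$k),
    family_id = kids$family_id,
    father_id = paste0(kids$family_id, "_P1"),
    mother_id = paste0(kids$family_id, "_P2"),
    sex = ifelse(stats::rbinom(nrow(kids), 1L, 0.5) == 1L, "M", "F"),
    role = "offspring"
  )
  ped <- dplyr::arrange(dplyr::bind_rows(founders, offspring),
                        .data$family_id, .data$role, .data$individual_id)
  validate_pedigree(ped)
  ped
}

validate_pedigree <- function(ped) {
  req <- c("individual_id", "family_id", "father_id", "mother_id", "sex")
  if (!all(req %in% names(ped))) {
    stop_invalid(paste("pedigree must have columns:", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(ped$individual_id)) stop_invalid("duplicate individual ids in pedigree")
  parents <- stats::na.omit(c(ped$father_id, ped$mother_id))
  if (!all(parents %in% ped$individual_id)) {
    stop_invalid("pedigree parent ids must refer to individuals in the table")
  }
  if (any(!is.na(ped$father_id) & ped$father_id == ped$individual_id) ||
      any(!is.na(ped$mother_id) & ped$mother_id == ped$individual_id)) {
    stop_invalid("an individual cannot be its own parent")
  }
  invisible(ped)
}

#' Write / read a pedigree as a FAM-like tab-separated file
#'
#' Columns: family, individual, father, mother, sex (1 = M, 2 = F); missing
#' parents written as `0`.
#'
#' @param ped Pedigree tibble from [simulate_pedigree()].
#' @param path Output path.
#' @return `write_pedigree()` returns `path` invisibly; `read_pedigree()`
#'   returns a pedigree tibble.
#' @export
write_pedigree <- function(ped, path) {
  validate_pedigree(ped)
  out <- tibble::tibble(
    family_id = ped$family_id,
    individual_id = ped$individual_id,
    father_id = ifelse(is.na(ped$father_id), "0", ped$father_id),
    mother_id = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    sex = ifelse(ped$sex == "M", 1L, 2L)
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  raw <- readr::read_tsv(path,
    col_names = c("family_id", "individual_id", "father_id", "mother_id", "sex"),
    col_types = "cccci",
    show_col_types = FALSE
  )
  ped <- tibble::tibble(
    individual_id = raw$individual_id,
    family_id = raw$family_id,
    father_id = ifelse(raw$father_id == "0", NA_character_, raw$father_id),
    mother_id = ifelse(raw$mother_id == "0", NA_character_, raw$mother_id),
    sex = ifelse(raw$sex == 1L, "M", "F"),
    role = ifelse(raw$father_id == "0" & raw$mother_id == "0", "founder", "offspring")
  )
  validate_pedigree(ped)
  ped
}
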