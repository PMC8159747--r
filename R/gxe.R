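#' Analysis plan for the PRS main-effect and interaction analyses
#'
#' Encodes the modeled outcomes (BMI and waist-circumference z-scores plus
#' their dichotomized versions), the environmental factors tested for
#' interaction with the PRS, the confounder set (sex, age, region of
#' residence, parental education, fruit/vegetable score as dietary proxy),
#' and the rule that fiber-exposure models drop the fruit/vegetable
#' covariate (both proxy healthy diet). Categorical terms are dummy-coded
#' against the largest-sample category; the FDR family is all interaction
#' contrasts within one outcome.
#'
#' @param outcomes Outcome column names.
#' @param exposures Exposures tested for PRS interaction.
#' @param confounders Adjustment set for every model.
#' @param min_stratum_children Minimum children per stratum for stratified
#'   fits (smaller strata are skipped with a message).
#' @return A list of class `analysis_plan`.
#' @export
analysis_plan <- function(outcomes = c("bmi_z", "wc_z", "obese", "wc_top"),
                          exposures = c("sex", "education", "region",
                                        "fruit_veg", "fiber", "mvpa",
                                        "screen_time"),
                          confounders = c("sex", "age", "region",
                                          "education", "fruit_veg"),
                          min_stratum_children = 50L) {
  structure(list(
    outcomes = outcomes,
    outcome_type = c(bmi_z = "continuous", wc_z = "continuous",
                     obese = "binary", wc_top = "binary")[outcomes],
    exposures = exposures,
    categorical = c("sex", "education", "region"),
    confounders = confounders,
    min_stratum_children = as.integer(min_stratum_children)
  ), class = "analysis_plan")
}

#' Build a model design for one outcome (optionally with a PRS interaction)
#'
#' Restricts to complete cases over the variables the model uses (listwise
#' deletion per model), dummy-codes categorical terms against the
#' largest-sample category, mean-centers continuous exposures before
#' forming PRS-by-exposure products, and re-standardizes the PRS over the
#' retained children so slopes are per SD of the analysis sample.
#'
#' @param pheno Phenotype tibble (one row per child-visit, columns per
#'   [simulate_phenotypes()] / [read_pheno()]).
#' @param prs PRS tibble from [standardize_prs()].
#' @param outcome Outcome column name.
#' @param exposure Optional exposure tested for interaction.
#' @param prs_scale `"z"` (continuous score) or `"top_decile"`.
#' @param plan An [analysis_plan()].
#' @param interaction Include the PRS-by-exposure product term(s)
#'   (default TRUE when `exposure` is given).
#' @param drop_terms Covariates to omit (used by stratified fits).
#' @return List: `y`, `X` (named matrix), `obs_individual`, `rows`
#'   (child/visit map), `outcome`, `exposure`, `interaction_terms`,
#'   `prs_term`, `type`.
#' @export
build_design <- function(pheno, prs, outcome, exposure = NULL,
                         prs_scale = c("z", "top_decile"),
                         plan = analysis_plan(),
                         interaction = !is.null(exposure),
                         drop_terms = NULL) {
  prs_scale <- match.arg(prs_scale)
  if (!outcome %in% names(pheno)) stop_invalid(paste("unknown outcome:", outcome))
  confounders <- setdiff(plan$confounders, drop_terms)
  if (!is.null(exposure) && exposure == "fiber") {
    confounders <- setdiff(confounders, "fruit_veg")  # both proxy healthy diet
  }
  df <- dplyr::left_join(pheno,
                         dplyr::select(prs, "individual_id", "z", "top_decile"),
                         by = c(child_id = "individual_id"))
  df$prs <- if (prs_scale == "z") df$z else df$top_decile

  vars <- unique(c(outcome, confounders, exposure, "prs"))
  cc <- complete.cases(df[, vars, drop = FALSE])
  if (!any(cc)) {
    miss <- vapply(df[, vars, drop = FALSE], function(x) sum(is.na(x)), integer(1))
    stop_failure(paste0("no complete cases; missing per column: ",
                        paste(names(miss), miss, sep = "=", collapse = ", ")))
  }
  df <- df[cc, , drop = FALSE]

  # largest-sample reference level, computed on the complete cases
  for (v in intersect(plan$categorical, c(confounders, exposure))) {
    f <- factor(df[[v]])
    df[[v]] <- stats::relevel(f, ref = names(which.max(table(f))))
  }
  # mean-center continuous exposures (so products leave main effects
  # interpretable); age stays in years
  for (v in intersect(c("fruit_veg", "fiber", "mvpa", "screen_time"),
                      c(confounders, exposure))) {
    df[[v]] <- df[[v]] - mean(df[[v]])
  }
  if (prs_scale == "z") {
    kid <- !duplicated(df$child_id)
    mu <- mean(df$prs[kid]); s <- sd(df$prs[kid])
    if (!is.finite(s) || s == 0) stop_failure("PRS has zero variance on the analysis sample")
    df$prs <- (df$prs - mu) / s
  }

  rhs <- c(confounders, setdiff(exposure, confounders), "prs")
  if (interaction && !is.null(exposure)) rhs <- c(rhs, paste0("prs:", exposure))
  fml <- stats::as.formula(paste("~", paste(rhs, collapse = " + ")))
  X <- model.matrix(fml, df)
  colnames(X)[colnames(X) == "(Intercept)"] <- "intercept"

  list(
    y = df[[outcome]], X = X, obs_individual = df$child_id,
    rows = tibble::tibble(child_id = df$child_id, visit = df$visit),
    outcome = outcome, exposure = exposure,
    interaction_terms = grep("(^prs:)|(:prs$)", colnames(X), value = TRUE),
    prs_term = "prs",
    type = if (all(df[[outcome]] %in% c(0, 1))) "binary" else "continuous"
  )
}

# fit one design, reusing a cached eigensystem when the rows match
fit_design <- function(design, kinship, ke_cache = NULL) {
  ke <- NULL
  if (!is.null(ke_cache)) {
    for (entry in ke_cache$entries) {
      if (identical(entry$obs, design$obs_individual)) { ke <- entry$ke; break }
    }
  }
  if (is.null(ke)) {
    ke <- if (inherits(kinship, "kinship_eigen") &&
              identical(kinship$obs_individual, design$obs_individual)) {
      kinship
    } else {
      kinship_eigen(kinship, design$obs_individual)
    }
    if (!is.null(ke_cache)) {
      ke_cache$entries <- c(ke_cache$entries,
                            list(list(obs = design$obs_individual, ke = ke)))
    }
  }
  if (design$type == "binary") {
    fit_logistic_pql(design$y, design$X, ke)
  } else {
    fit_lmm(design$y, design$X, ke)
  }
}

#' PRS main-effect analysis across outcomes
#'
#' For each outcome and PRS scale (continuous z-score and top-decile
#' indicator): the adjusted PRS coefficient with 95% CI and Wald p
#' (beta scale for continuous outcomes, odds-ratio scale for binary ones),
#' plus the incremental whitened r-squared (continuous) or the
#' fixed-effect-linear-predictor AUC (binary).
#'
#' @param pheno,prs,kinship Data inputs (see [build_design()]); `kinship`
#'   is an individual-level [grm_standardized()] result (or precomputed
#'   [kinship_eigen()]).
#' @param plan An [analysis_plan()].
#' @param prs_scales Subset of `c("z", "top_decile")`.
#' @return Tibble: one row per outcome x scale with `estimate`, `conf.low`,
#'   `conf.high`, `p.value`, `r2`, `auc`, sizes.
#' @export
main_effect_analysis <- function(pheno, prs, kinship, plan = analysis_plan(),
                                 prs_scales = c("z", "top_decile")) {
  ke_cache <- new.env()
  ke_cache$entries <- list()
  grid <- tidyr::expand_grid(outcome = plan$outcomes, scale = prs_scales)
  purrr::pmap_dfr(grid, function(outcome, scale) {
    d <- build_design(pheno, prs, outcome, prs_scale = scale, plan = plan)
    fit <- fit_design(d, kinship, ke_cache)
    w <- wald(fit, d$prs_term, or_scale = d$type == "binary")
    tibble::tibble(
      outcome = outcome, prs_scale = scale, type = d$type,
      estimate = w$estimate, conf.low = w$conf.low, conf.high = w$conf.high,
      p.value = w$p.value,
      r2 = if (d$type == "continuous") incremental_r2(fit, d) else NA_real_,
      auc = if (d$type == "binary") {
        auc(drop(d$X %*% coef(fit)), d$y)
      } else NA_real_,
      n_obs = fit$n_obs, n_children = fit$n_individuals
    )
  })
}

#' PRS-by-environment interaction analysis with FDR
#'
#' Fits, per outcome and exposure, the adjusted model with PRS-by-exposure
#' product term(s) and Wald-tests each interaction coefficient. Continuous
#' exposures contribute one product term; categorical exposures one per
#' non-reference level. Benjamini-Hochberg adjustment is applied across all
#' interaction contrasts within an outcome (the family of tested
#' environmental factors).
#'
#' @inheritParams main_effect_analysis
#' @param outcomes Outcomes to test (default: the plan's continuous ones).
#' @return Tibble: `outcome`, `exposure`, `term`, `estimate`, `conf.low`,
#'   `conf.high`, `p.value`, `q.value`, `n_obs`.
#' @export
interaction_analysis <- function(pheno, prs, kinship, plan = analysis_plan(),
                                 outcomes = plan$outcomes[plan$outcome_type ==
                                                            "continuous"]) {
  ke_cache <- new.env()
  ke_cache$entries <- list()
  res <- purrr::map_dfr(outcomes, function(oc) {
    purrr::map_dfr(plan$exposures, function(ex) {
      d <- build_design(pheno, prs, oc, exposure = ex, plan = plan)
      fit <- fit_design(d, kinship, ke_cache)
      w <- wald(fit, d$interaction_terms)
      dplyr::mutate(w, outcome = oc, exposure = ex, n_obs = fit$n_obs,
                    .before = 1)
    })
  })
  dplyr::mutate(dplyr::group_by(res, .data$outcome),
                q.value = bh_adjust(.data$p.value)) |>
    dplyr::ungroup() |>
    dplyr::relocate("q.value", .after = "p.value")
}

#' Exposure-stratified PRS slopes
#'
#' Refits the main-effect model inside each level of a categorical exposure
#' (dropping the stratifying covariate from the adjustment set) and reports
#' the per-stratum PRS slope with 95% CI — the stratified companion to the
#' interaction test. Strata with fewer children than the plan minimum are
#' skipped with a message.
#'
#' @inheritParams main_effect_analysis
#' @param outcome Outcome column.
#' @param exposure Categorical exposure to stratify on.
#' @return Tibble of class `prsgxe_strata`: `stratum`, `estimate`,
#'   `conf.low`, `conf.high`, `p.value`, `n_obs`, `n_children`.
#' @export
stratified_analysis <- function(pheno, prs, kinship, outcome, exposure,
                                plan = analysis_plan()) {
  if (!exposure %in% plan$categorical) {
    stop_invalid("stratified analysis requires a categorical exposure")
  }
  levs <- sort(unique(as.character(pheno[[exposure]])))
  out <- purrr::map_dfr(levs, function(lv) {
    sub <- pheno[!is.na(pheno[[exposure]]) & pheno[[exposure]] == lv, ,
                 drop = FALSE]
    n_kid <- length(unique(sub$child_id))
    if (n_kid < plan$min_stratum_children) {
      inform(sprintf("stratum %s=%s skipped: %d children < minimum %d",
                     exposure, lv, n_kid, plan$min_stratum_children))
      return(tibble::tibble())
    }
    d <- build_design(sub, prs, outcome, plan = plan, drop_terms = exposure)
    fit <- fit_design(d, kinship)
    w <- wald(fit, d$prs_term, or_scale = d$type == "binary")
    tibble::tibble(
      stratum = lv, estimate = w$estimate, conf.low = w$conf.low,
      conf.high = w$conf.high, p.value = w$p.value,
      n_obs = fit$n_obs, n_children = fit$n_individuals
    )
  })
  structure(out, class = c("prsgxe_strata", class(out)),
            outcome = outcome, exposure = exposure)
}

#' Benjamini-Hochberg q values
#'
#' Step-up FDR adjustment: order the m p values ascending, set
#' `q_(i) = min_{j >= i} p_(j) * m / j` capped at 1, and map back to the
#' input order.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return q values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop_invalid("p values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(p[ord] * m / seq_len(m), 1)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Incremental (whitened) r-squared of the PRS
#'
#' Whitens response and design by the full model's fitted covariance (via
#' the model's eigensystem at the fitted variance ratio) and reports
#' `(RSS_reduced - RSS_full) / RSS_reduced`, the share of whitened residual
#' variation explained by the PRS term(s) on top of the covariates.
#'
#' @param fit The full-model `prsgxe_fit` (from [fit_lmm()]).
#' @param design The [build_design()] output the fit came from.
#' @param prs_cols Columns treated as the PRS block (default: the PRS term
#'   and any of its products).
#' @return Numeric r-squared in `[0, 1]`.
#' @export
incremental_r2 <- function(fit, design, prs_cols = NULL) {
  stopifnot(inherits(fit, "prsgxe_fit"))
  if (fit$link != "identity") stop_invalid("incremental r2 is defined for linear fits")
  if (is.null(prs_cols)) {
    prs_cols <- c(design$prs_term, design$interaction_terms)
  }
  prs_cols <- intersect(prs_cols, colnames(design$X))
  if (length(prs_cols) == 0) stop_invalid("no PRS columns found in the design")
  Xr <- design$X[, setdiff(colnames(design$X), prs_cols), drop = FALSE]
  ke <- fit$eigen
  delta <- exp(fit$log_delta)
  rss_full <- gls_at_delta(rotated_stats(design$y, design$X, ke), ke, delta)$rss
  rss_red <- gls_at_delta(rotated_stats(design$y, Xr, ke), ke, delta)$rss
  if (rss_red <= 0) stop_failure("reduced model has zero residual variation")
  max((rss_red - rss_full) / rss_red, 0)
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' `U / (n1 n0)` with ties counted one half, computed from midranks.
#'
#' @param scores Numeric predictor.
#' @param labels Binary 0/1 outcomes (both classes present).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop_failure("both outcome classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
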