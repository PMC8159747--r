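#' Tidy a mixed-model fit
#'
#' @param x A `prsgxe_fit`.
#' @param or_scale Exponentiate estimates/CIs (logistic fits).
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`, `se`, `conf.low`,
#'   `conf.high`, `statistic`, `p.value`.
#' @method tidy prsgxe_fit
#' @export
tidy.prsgxe_fit <- function(x, or_scale = FALSE, ...) {
  wald(x, or_scale = or_scale)
}

#' One-row model summary
#'
#' @param x A `prsgxe_fit`.
#' @param ... Unused.
#' @return Tibble with variance components, log-likelihood, sizes and flags.
#' @method glance prsgxe_fit
#' @export
glance.prsgxe_fit <- function(x, ...) {
  tibble::tibble(
    link = x$link, method = x$method,
    sigma2_g = x$sigma2_g, sigma2_e = x$sigma2_e,
    logLik = x$loglik, n_obs = x$n_obs, n_individuals = x$n_individuals,
    converged = x$converged, boundary = x$boundary
  )
}

#' @export
coef.prsgxe_fit <- function(object, ...) object$coefficients

#' @export
vcov.prsgxe_fit <- function(object, ...) object$vcov
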