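#' Forest plot of stratified PRS slopes
#'
#' One point and 95% CI per stratum of the stratifying factor, with an
#' optional whole-population reference line.
#'
#' @param object A `prsgxe_strata` tibble from [stratified_analysis()].
#' @param overall Optional whole-population slope drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prsgxe_strata
#' @export
autoplot.prsgxe_strata <- function(object, overall = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$estimate, y = .data$stratum)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(
      x = sprintf("PRS slope on %s (per SD, 95%% CI)", attr(object, "outcome")),
      y = attr(object, "exposure")
    ) +
    ggplot2::theme_minimal()
  if (!is.null(overall)) {
    p <- p + ggplot2::geom_vline(xintercept = overall, colour = "red",
                                 linetype = 2)
  }
  p
}

#' PRS slope as a function of a continuous exposure
#'
#' Visualizes an interaction result: the fitted PRS slope
#' `beta_prs + beta_gxe * (E - mean(E))` across the observed exposure range
#' with a pointwise 95% band from the interaction fit's covariance.
#'
#' @param fit A `prsgxe_fit` from an interaction model.
#' @param design The matching [build_design()] output (continuous exposure).
#' @param n_grid Grid points across the centered exposure range.
#' @return A ggplot object.
#' @export
plot_interaction_slope <- function(fit, design, n_grid = 100) {
  term <- design$interaction_terms
  if (length(term) != 1) {
    stop_invalid("slope plot requires a single continuous interaction term")
  }
  e_col <- design$exposure
  e <- design$X[, e_col]
  grid <- seq(min(e), max(e), length.out = n_grid)
  b <- coef(fit)[c(design$prs_term, term)]
  V <- fit$vcov[c(design$prs_term, term), c(design$prs_term, term)]
  slope <- b[1] + b[2] * grid
  se <- sqrt(V[1, 1] + grid^2 * V[2, 2] + 2 * grid * V[1, 2])
  df <- tibble::tibble(exposure = grid, slope = slope,
                       lo = slope - 1.96 * se, hi = slope + 1.96 * se)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$exposure, y = .data$slope)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = paste(e_col, "(centered)"),
                  y = sprintf("PRS slope on %s (per SD)", design$outcome)) +
    ggplot2::theme_minimal()
}
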