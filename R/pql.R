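#' Fit a kinship-aware logistic mixed model by penalized quasi-likelihood
#'
#' Binary outcomes are modeled with a logit link and the same
#' GRM-structured random intercept as [fit_lmm()]. Estimation follows the
#' classical PQL scheme: iterate (i) working response
#' `z = eta + (y - mu) / (mu (1 - mu))` and weights `W = mu (1 - mu)` from
#' the current linear predictor (fixed plus BLUP random effect), (ii) a
#' weighted linear mixed fit of `z` with covariance
#' `sigma2_g * Sigma_obs + W^{-1}` via the same eigendecomposition
#' machinery (the binomial dispersion is fixed at 1 and only `sigma2_g` is
#' profiled), until the coefficients move by less than `tol` or `maxit`
#' iterations. PQL is known to bias variance components toward zero for
#' rare binary outcomes; see the package vignette.
#'
#' @param y Binary 0/1 response (no NA).
#' @param X Design matrix, full column rank.
#' @param kinship `kinship` object, dense observation-level covariance, or
#'   `kinship_eigen` (its kinship and observation map are reused).
#' @param obs_individual Observation-to-individual map.
#' @param maxit,tol Iteration controls (`max |delta beta| < tol` stops).
#' @param fix_sigma2_g Optionally pin the genetic variance (0 reduces the
#'   fit to plain logistic IRLS).
#' @return A `prsgxe_fit` with `link = "logit"`.
#' @export
fit_logistic_pql <- function(y, X, kinship, obs_individual = NULL,
                             maxit = 50L, tol = 1e-6, fix_sigma2_g = NULL) {
  if (anyNA(y) || !all(y %in% c(0, 1))) stop_invalid("y must be 0/1 with no missing values")
  if (length(unique(y)) < 2) stop_failure("no variation in the binary outcome")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(y)) stop_invalid("nrow(X) must equal length(y)")
  check_full_rank(X)

  if (inherits(kinship, "kinship_eigen")) {
    V <- new_kinship(kinship$Vsub)
    obs_individual <- kinship$obs_individual
  } else if (inherits(kinship, "kinship")) {
    V <- kinship
    if (is.null(obs_individual)) obs_individual <- kinship$ids
  } else {
    V <- new_kinship(as_named_matrix(kinship))
    if (is.null(obs_individual)) obs_individual <- V$ids
  }
  n <- length(y)
  pinned <- !is.null(fix_sigma2_g)
  if (pinned && fix_sigma2_g < 0) stop_invalid("fix_sigma2_g must be >= 0")

  mu <- (y + 0.5) / 2
  eta <- qlogis(mu)
  eta_prev <- eta_prev2 <- NULL
  just_accelerated <- FALSE
  beta <- rep(0, ncol(X))
  sg <- if (pinned) fix_sigma2_g else 0.1
  loglik <- NA_real_
  converged <- FALSE
  ke_w <- NULL
  delta <- NA_real_
  vcov <- NULL
  iter <- 0L

  for (iter in seq_len(maxit)) {
    w <- pmin(pmax(mu * (1 - mu), 1e-6), 0.25)
    z <- eta + (y - mu) / w
    beta_old <- beta

    if (pinned && fix_sigma2_g == 0) {
      A <- crossprod(X, X * w)
      R <- chol(A)
      beta <- backsolve(R, forwardsolve(t(R), crossprod(X, z * w)))
      vcov <- chol2inv(R)
      u_obs <- 0
      loglik <- sum(stats::dbinom(y, 1, plogis(drop(X %*% beta)), log = TRUE))
    } else {
      ke_w <- kinship_eigen(V, obs_individual, weights = w)
      rs <- rotated_stats(z, X, ke_w)
      logdetXtWX <- 2 * sum(log(diag(chol(rs$XtX))))
      crit <- function(log_sg) {
        s <- exp(log_sg)
        g <- gls_at_delta(rs, ke_w, 1 / s)
        if (is.null(g)) return(-Inf)
        # REML criterion of the working model at dispersion 1:
        # V_full = s * (Sigma_tilde + I/s)
        -0.5 * ((n - rs$p) * log(s) + g$logdetSig + g$logdetA -
                  logdetXtWX + g$rss / s)
      }
      if (pinned) {
        log_sg <- log(fix_sigma2_g)
      } else {
        opt <- optimize(crit, c(-10, 10), maximum = TRUE, tol = 1e-10)
        cand <- c(opt$maximum, -10, 10)
        vals <- c(opt$objective, crit(-10), crit(10))
        log_sg <- cand[which.max(vals)]
      }
      sg <- exp(log_sg)
      delta <- 1 / sg
      g <- gls_at_delta(rs, ke_w, delta)
      beta <- g$beta
      vcov <- sg * chol2inv(g$R)
      loglik <- crit(log_sg)
      # BLUP of the individual random effects:
      # u = V Z~' (Sigma~ + delta I)^{-1} (z~ - X~ beta)
      sw <- sqrt(w)
      rt <- (z - drop(X %*% beta)) * sw
      Btr <- drop(crossprod(ke_w$B, rt))
      sol <- drop(ke_w$B %*% (Btr / (ke_w$mu + delta))) +
        (rt - drop(ke_w$B %*% Btr)) / delta
      ztr <- as.vector(tapply(sw * sol,
                              factor(ke_w$jidx, levels = seq_len(ke_w$n_ind)),
                              sum))
      u_ind <- drop(ke_w$Vsub %*% ztr)
      u_obs <- u_ind[ke_w$jidx]
    }

    eta <- drop(X %*% beta) + u_obs
    # Aitken extrapolation: the PQL map converges linearly, sometimes with a
    # ratio near 1; extrapolating the eta sequence along its dominant
    # direction leaves the fixed point unchanged but reaches it fast
    if (!just_accelerated && !is.null(eta_prev2)) {
      d1 <- eta_prev - eta_prev2
      d2 <- eta - eta_prev
      ratio <- sum(d1 * d2) / max(sum(d1 * d1), 1e-300)
      if (is.finite(ratio) && ratio > 0.2 && ratio < 1.05 &&
          max(abs(d2)) < 1) {
        gain <- if (ratio >= 1) 20 else min(ratio / (1 - ratio), 20)
        eta <- pmin(pmax(eta + gain * d2, -30), 30)
        just_accelerated <- TRUE
      } else {
        just_accelerated <- FALSE
      }
    } else {
      just_accelerated <- FALSE
    }
    eta_prev2 <- eta_prev
    eta_prev <- eta
    mu <- plogis(eta)
    if (max(abs(beta)) > 50) {
      stop_failure("separation detected: coefficients diverging")
    }
    if (max(abs(beta - beta_old)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("PQL did not converge in %d iterations (max |delta beta| tol %g)",
                 maxit, tol))
  }

  beta <- drop(beta)
  names(beta) <- colnames(X)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(list(
    coefficients = beta, se = sqrt(pmax(diag(vcov), 0)), vcov = vcov,
    sigma2_g = if (pinned) fix_sigma2_g else sg, sigma2_e = NA_real_,
    dispersion = 1, log_delta = if (is.na(delta)) NA_real_ else log(delta),
    loglik = loglik, method = "PQL", link = "logit",
    converged = converged, boundary = !pinned && abs(abs(log(sg)) - 10) < 1e-3,
    n_obs = n, n_individuals = length(unique(obs_individual)),
    df_residual = n - ncol(X), n_iter = iter
  ), class = "prsgxe_fit")
}

as_named_matrix <- function(M) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  if (is.null(rownames(M))) {
    rownames(M) <- colnames(M) <- paste0("obs", seq_len(nrow(M)))
  }
  M
}
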