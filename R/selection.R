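#' Information rate of bilinear axes
#'
#' `IR_k = lambda_k^2 / (sum(lambda^2) / t)`: the share of the total
#' squared singular values carried by axis `k`, relative to the share an
#' uninformative axis would carry. `IR_k > 1` flags an axis that summarizes
#' structure beyond a single variable's worth and should be kept; once
#' `IR_k < 1` that axis and all later ones read as noise. The rates sum to
#' `t` by construction.
#'
#' @param lambda nonnegative singular values (length `t`).
#' @param t number of axes; defaults to `length(lambda)`.
#' @return Numeric vector of information rates.
#' @export
information_rate <- function(lambda, t = length(lambda)) {
  if (any(lambda < 0)) stop("singular values must be nonnegative",
                            call. = FALSE)
  tot <- sum(lambda^2)
  if (tot == 0) stop("all singular values are zero", call. = FALSE)
  lambda^2 / (tot / t)
}

#' Variance shares of bilinear axes
#'
#' `share_k = lambda_k^2 / sum(lambda^2)`; sums to 1. The cumulative sum of
#' the first components is the usual "percentage of G+GE explained".
#'
#' @param lambda nonnegative singular values, not all zero.
#' @return Vector of proportions.
#' @export
variance_share <- function(lambda) {
  if (any(lambda < 0)) stop("singular values must be nonnegative",
                            call. = FALSE)
  tot <- sum(lambda^2)
  if (tot == 0) stop("all singular values are zero", call. = FALSE)
  lambda^2 / tot
}

# free parameters: b*l block effects + rank-k bilinear term + residual var
df_bgge <- function(v, l, b, k) b * l + k * (v + l - k) + 1

#' AIC and BIC of a fitted Bayesian GGE model
#'
#' Plug-in criteria evaluated at the posterior means of all parameters
#' (loading matrices re-orthonormalized after averaging):
#' `AIC = -2 loglik + 2 df` and `BIC = -2 loglik + df log(n)` with
#' `df = b*l + k(v + l - k) + 1`, the free-parameter count of a rank-`k`
#' SVD plus linear terms and the residual variance. Lower is better.
#'
#' @param fit a fitted [bgge()] model.
#' @return Named vector with `AIC`, `BIC`, `df` and the plug-in `loglik`.
#' @export
aic_bic <- function(fit) {
  met <- fit$met
  cf <- coef(fit)
  A <- orthonormalize_cols(cf$A)
  G <- orthonormalize_cols(cf$G)
  lam <- sort(pmax(cf$lambda, 0), decreasing = TRUE)
  st <- param_state(cf$beta, lam, A, G, cf$sigma2_e)
  ll <- loglik(st, fit$design)
  df <- df_bgge(met$v, met$l, met$b, fit$cfg$k)
  c(AIC = -2 * ll + 2 * df, BIC = -2 * ll + df * log(met$n),
    df = df, loglik = ll)
}

#' Monte Carlo Akaike criterion from posterior log-likelihood draws
#'
#' `AICM = 2 * var(l) - 2 * mean(l)` over the retained log-likelihood
#' draws; the posterior variance of the log-likelihood acts as the
#' effective-parameter penalty. Lower is better.
#'
#' @param loglik_draws numeric vector of at least 2 posterior
#'   log-likelihood values, or a fitted [bgge()] model.
#' @return Scalar AICM.
#' @export
aicm <- function(loglik_draws) {
  if (inherits(loglik_draws, "bgge_chain"))
    loglik_draws <- loglik_draws$draws$loglik
  if (length(loglik_draws) < 2L) stop("need at least 2 draws", call. = FALSE)
  2 * stats::var(loglik_draws) - 2 * mean(loglik_draws)
}

# kernel-density posterior mode of a scalar sample
posterior_mode <- function(x) {
  if (stats::var(x) == 0) return(x[1])
  d <- stats::density(x)
  d$x[which.max(d$y)]
}

#' Residual-variance profile across model dimensions
#'
#' The kernel-density posterior mode of the residual variance for each
#' fitted dimension `k`. Once the profile flattens, added bilinear axes no
#' longer absorb systematic variation and only refit noise.
#'
#' @param fits list of fitted [bgge()] models (one per `k`).
#' @return Named numeric vector of posterior modes, ordered as `fits`.
#' @export
sigma_profile <- function(fits) {
  out <- vapply(fits, function(f) posterior_mode(f$draws$sigma2_e),
                numeric(1))
  names(out) <- vapply(fits, function(f) paste0("k", f$cfg$k), character(1))
  out
}

#' Model-selection table across bilinear dimensions
#'
#' Fits (or accepts pre-fitted) models for a grid of `k` and tabulates AIC,
#' BIC, AICM, the posterior mode of the residual variance and the variance
#' share of each component.
#'
#' @param fits list of fitted [bgge()] models.
#' @return Data frame with one row per fitted dimension.
#' @export
selection_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    ab <- aic_bic(f)
    data.frame(k = f$cfg$k, AIC = ab["AIC"], BIC = ab["BIC"],
               AICM = aicm(f),
               sigma2_e_mode = posterior_mode(f$draws$sigma2_e),
               share12 = sum(variance_share(
                 colMeans(f$draws$lambda))[seq_len(min(2L, f$cfg$k))]),
               row.names = NULL)
  })
  do.call(rbind, rows)
}
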