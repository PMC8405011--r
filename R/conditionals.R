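#' Model configuration for the Bayesian GGE fit
#'
#' Two prior regimes are supported for the singular values of the bilinear
#' term. Under the `"flat"` variant the half-normal prior on each singular
#' value has a fixed huge variance (`sigma2_lambda = 1e8`), so the posterior
#' essentially reproduces the likelihood solution. Under the `"entropy"`
#' variant each singular-value variance gets a maximum-entropy hierarchical
#' prior, whose full conditional is inverse-gamma with shape `a + 1` and
#' scale `lambda_k^2 + 2 b_scale`; with the derived values `a = 1`,
#' `b_scale = 0` this shrinks weakly-supported singular values toward zero.
#'
#' @param variant `"flat"` (non-shrinkage) or `"entropy"` (shrinkage).
#' @param k number of bilinear components retained (`1..t`).
#' @param sigma2_beta prior variance of the block-within-environment effects.
#' @param sigma2_lambda fixed singular-value prior variance (flat variant).
#' @param a,b_scale hyperparameters of the entropy-variant hierarchical prior.
#' @param sigma2_lambda_floor numerical floor on the sampled singular-value
#'   variance; keeps the next singular-value conditional proper when a
#'   singular value has collapsed to zero.
#' @return Object of class `"bgge_config"`.
#' @export
model_config <- function(variant = c("entropy", "flat"), k,
                         sigma2_beta = 1e8, sigma2_lambda = 1e8,
                         a = 1, b_scale = 0, sigma2_lambda_floor = 1e-12) {
  variant <- match.arg(variant)
  k <- as.integer(k)
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  stopifnot(sigma2_beta > 0, sigma2_lambda > 0, sigma2_lambda_floor > 0)
  structure(list(variant = variant, k = k, sigma2_beta = sigma2_beta,
                 sigma2_lambda = sigma2_lambda, a = a, b_scale = b_scale,
                 sigma2_lambda_floor = sigma2_lambda_floor),
            class = "bgge_config")
}

#' One state of the Gibbs sampler
#'
#' Bundles a draw of all model parameters: `beta` (block-within-environment
#' effects, length `b*l`), `lambda` (ordered nonnegative singular values,
#' length `k`), `A` (`v x k` genotype loadings), `G` (`l x k` environment
#' loadings), `sigma2_e` (residual variance) and, under the entropy variant,
#' `sigma2_lambda` (length `k`).
#'
#' @param beta,lambda,A,G,sigma2_e,sigma2_lambda see description.
#' @return Object of class `"param_state"`.
#' @export
param_state <- function(beta, lambda, A, G, sigma2_e, sigma2_lambda = NULL) {
  structure(list(beta = beta, lambda = lambda, A = as.matrix(A),
                 G = as.matrix(G), sigma2_e = sigma2_e,
                 sigma2_lambda = sigma2_lambda),
            class = "param_state")
}

# n-vector of the k-th bilinear regressor: diag(Z alpha_k) X2 gamma_k
bilinear_column <- function(state, design, k) {
  state$A[design$gi, k] * state$G[design$ei, k]
}

# n x k matrix of all bilinear regressors, and the full bilinear fit M
bilinear_frame <- function(state, design) {
  K <- length(state$lambda)
  L <- state$A[design$gi, , drop = FALSE] * state$G[design$ei, , drop = FALSE]
  list(L = L, M = as.vector(L %*% state$lambda))
}

#' Full conditional of the block-within-environment effects
#'
#' Normal with mean `(X1'X1 + (sigma2_e/sigma2_beta) I)^-1 X1'(y - M)` and
#' covariance `(X1'X1 + (sigma2_e/sigma2_beta) I)^-1 sigma2_e`, where `M` is
#' the current bilinear fit. `X1` is an incidence matrix, so the precision is
#' diagonal and the covariance is returned as a variance vector.
#'
#' @param state a [param_state()].
#' @param design a [build_design()] object.
#' @param cfg a [model_config()].
#' @return List of class `"normal_spec"` with `mean` and `var` vectors.
#' @export
cond_beta <- function(state, design, cfg) {
  resid <- design$y - bilinear_frame(state, design)$M
  p <- design$met$b * design$met$l
  counts <- tabulate(design$x1i, p)
  prec <- counts + state$sigma2_e / cfg$sigma2_beta
  s <- group_sum(resid, design$x1i, p)
  structure(list(mean = s / prec, var = state$sigma2_e / prec),
            class = c("normal_spec", "cond_spec"))
}

#' Full conditional of the k-th singular value
#'
#' Truncated normal. Location and squared scale follow the conjugate normal
#' update with ridge term `sigma2_e / sigma2_lambda_k`; the truncation
#' interval `[lambda_(k+1), lambda_(k-1)]` enforces the order constraint
#' `lambda_1 >= ... >= lambda_K >= 0`.
#'
#' @inheritParams cond_beta
#' @param k component index.
#' @return List of class `"trunc_normal_spec"` with `location`, `scale2`,
#'   `lower`, `upper`.
#' @export
cond_lambda <- function(state, design, cfg, k) {
  K <- length(state$lambda)
  stopifnot(k >= 1L, k <= K)
  Lk <- bilinear_column(state, design, k)
  resid <- design$y - beta_fit(state, design)
  if (K > 1L) {
    others <- setdiff(seq_len(K), k)
    for (j in others) resid <- resid -
        state$lambda[j] * bilinear_column(state, design, j)
  }
  s2l <- sigma2_lambda_k(state, cfg, k)
  prec <- sum(Lk * Lk) + state$sigma2_e / s2l
  if (prec <= 0) stop("nonpositive precision in lambda conditional")
  structure(list(location = sum(Lk * resid) / prec,
                 scale2 = state$sigma2_e / prec,
                 lower = if (k < K) state$lambda[k + 1L] else 0,
                 upper = if (k > 1L) state$lambda[k - 1L] else Inf),
            class = c("trunc_normal_spec", "cond_spec"))
}

beta_fit <- function(state, design) state$beta[design$x1i]

sigma2_lambda_k <- function(state, cfg, k) {
  if (cfg$variant == "flat") cfg$sigma2_lambda
  else max(state$sigma2_lambda[k], cfg$sigma2_lambda_floor)
}

#' Full conditional of the k-th singular-value variance (entropy variant)
#'
#' Inverse-gamma with shape `a + 1` and scale `lambda_k^2 + 2 b_scale`,
#' in the convention of [rinv_gamma2()] (density proportional to
#' `x^-(shape+1) exp(-scale2/(2x))`). The scale is floored at
#' `sigma2_lambda_floor` so a collapsed singular value does not make the
#' next conditional degenerate.
#'
#' @inheritParams cond_lambda
#' @return List of class `"inv_gamma_spec"` with `shape` and `scale2`.
#' @export
cond_sigma_lambda <- function(state, cfg, k) {
  if (cfg$variant != "entropy")
    stop("sigma2_lambda is only sampled under the entropy variant",
         call. = FALSE)
  structure(list(shape = cfg$a + 1,
                 scale2 = max(state$lambda[k]^2 + 2 * cfg$b_scale,
                              cfg$sigma2_lambda_floor)),
            class = c("inv_gamma_spec", "cond_spec"))
}

#' Full conditional of a singular vector (von Mises-Fisher)
#'
#' The conditional density of a genotype loading `alpha_k` (or environment
#' loading `gamma_k`) is proportional to
#' `exp{(lambda_k / sigma2_e) * v' L*'(y - X1 beta)}` on the unit sphere,
#' restricted to the orthogonal complement of the other same-side loadings.
#' Sampling happens in that corrected subspace: with `H` an orthonormal
#' basis of the complement and `h = H' L*'(y - X1 beta)`, the auxiliary
#' vector is vMF with concentration `||h|| lambda_k / sigma2_e` and mean
#' direction `h / ||h||`, and the draw is mapped back by `H`.
#'
#' @inheritParams cond_lambda
#' @param side `"genotypic"` (alpha) or `"environmental"` (gamma).
#' @return List of class `"vmf_spec"` with `m` (subspace dimension),
#'   `kappa`, `mu` (unit mean direction in the subspace), `H` (basis),
#'   `k` and `p = k - 1`.
#' @export
cond_vector <- function(state, design, cfg, k,
                        side = c("genotypic", "environmental")) {
  side <- match.arg(side)
  K <- length(state$lambda)
  stopifnot(k >= 1L, k <= K)
  resid <- design$y - beta_fit(state, design)
  if (side == "genotypic") {
    raw_all <- state$G[design$ei, k] * resid
    mu_raw <- group_sum(raw_all, design$gi, design$met$v)
    V <- state$A[, -k, drop = FALSE]
  } else {
    raw_all <- state$A[design$gi, k] * resid
    mu_raw <- group_sum(raw_all, design$ei, design$met$l)
    V <- state$G[, -k, drop = FALSE]
  }
  H <- orthonormal_complement(V)
  h <- as.vector(crossprod(H, mu_raw))
  hn <- sqrt(sum(h * h))
  m <- ncol(H)
  if (hn < 1e-300) {
    mu <- c(1, rep(0, m - 1L))
    kappa <- 0
  } else {
    mu <- h / hn
    kappa <- hn * state$lambda[k] / state$sigma2_e
  }
  structure(list(m = m, kappa = kappa, mu = mu, H = H, k = k, p = k - 1L,
                 side = side),
            class = c("vmf_spec", "cond_spec"))
}

group_sum <- function(x, idx, ngroups) {
  out <- numeric(ngroups)
  s <- rowsum(x, idx, reorder = TRUE)
  out[as.integer(rownames(s))] <- s
  out
}

#' Full conditional of the residual variance
#'
#' Scaled inverse chi-square with `n` degrees of freedom and scale
#' `SSE / n`, where `SSE` is the residual sum of squares at the current
#' fitted mean (Jeffreys prior on `sigma2_e`).
#'
#' @inheritParams cond_beta
#' @return List of class `"scaled_inv_chisq_spec"` with `df` and `scale`.
#' @export
cond_sigma_e <- function(state, design) {
  mu_y <- beta_fit(state, design) + bilinear_frame(state, design)$M
  sse <- sum((design$y - mu_y)^2)
  structure(list(df = design$met$n, scale = sse / design$met$n),
            class = c("scaled_inv_chisq_spec", "cond_spec"))
}
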