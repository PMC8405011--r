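#' MCMC plan for the Gibbs sampler
#'
#' The total chain length is `N = n_keep * thin + burn_in`: after discarding
#' `burn_in` iterations, every `thin`-th state is retained until `n_keep`
#' draws are stored. The defaults mirror the planning rule used for the
#' reference analyses (pilot of 4000, thinning set to the largest
#' Raftery-Lewis dependence factor, burn-in at least 10000); substantially
#' shorter plans are appropriate for toy problems and cross-validation
#' refits.
#'
#' @param n_keep retained draws after thinning.
#' @param thin thinning interval `J >= 1`.
#' @param burn_in discarded initial iterations `B`.
#' @param pilot pilot-chain size used when planning from diagnostics.
#' @param q,r,s Raftery-Lewis quantile, precision and probability settings.
#' @param I_max acceptance cap on the Raftery-Lewis dependence factor.
#' @param hw_alpha significance level of the Heidelberger-Welch tests.
#' @return Object of class `"mcmc_plan"` with the above fields plus the
#'   implied total `N`.
#' @export
mcmc_plan <- function(n_keep = 4000L, thin = 20L, burn_in = 10000L,
                      pilot = 4000L, q = 0.025, r = 0.005, s = 0.95,
                      I_max = 5, hw_alpha = 0.05) {
  thin <- as.integer(thin); burn_in <- as.integer(burn_in)
  n_keep <- as.integer(n_keep)
  if (thin < 1L) stop("thin must be >= 1", call. = FALSE)
  structure(list(n_keep = n_keep, thin = thin, burn_in = burn_in,
                 pilot = as.integer(pilot), q = q, r = r, s = s,
                 I_max = I_max, hw_alpha = hw_alpha,
                 N = n_keep * thin + burn_in),
            class = "mcmc_plan")
}

#' Gaussian log-likelihood of the GGE model at one parameter state
#'
#' `-(n/2) log(2 pi sigma2_e) - SSE / (2 sigma2_e)` with the fitted mean
#' `X1 beta + sum_k lambda_k diag(Z alpha_k) X2 gamma_k`.
#'
#' @param state a [param_state()].
#' @param design a [build_design()] object.
#' @return Scalar log-likelihood.
#' @export
loglik <- function(state, design) {
  if (state$sigma2_e <= 0) stop("sigma2_e must be positive", call. = FALSE)
  mu_y <- beta_fit(state, design) + bilinear_frame(state, design)$M
  n <- design$met$n
  -0.5 * n * log(2 * pi * state$sigma2_e) -
    sum((design$y - mu_y)^2) / (2 * state$sigma2_e)
}

# Initial state: frequentist SVD of the environment-centered cell-mean
# matrix (empty cells filled with 0 before centering, for initialization
# only), block-within-environment means for beta, residual variance of that
# fit for sigma2_e.
init_state <- function(design, cfg) {
  met <- design$met
  rec <- met$records
  sums <- tapply(rec$response, list(rec$genotype, rec$environment), sum)
  cnt <- met$cell_counts
  means <- ifelse(cnt > 0L, sums / pmax(cnt, 1L), 0)
  centered <- sweep(means, 2L, colMeans(means))
  sv <- svd_gge(centered)
  K <- cfg$k
  lambda <- pmax(sv$lambda[seq_len(K)], 1e-8)
  lambda <- rev(cummax(rev(lambda)))   # enforce ordering after the floor
  A <- sv$A[, seq_len(K), drop = FALSE]
  G <- sv$G[, seq_len(K), drop = FALSE]
  p <- met$b * met$l
  counts <- tabulate(design$x1i, p)
  beta <- group_sum(design$y, design$x1i, p) / pmax(counts, 1L)
  beta[counts == 0L] <- mean(design$y)
  M <- as.vector((A[design$gi, , drop = FALSE] *
                    G[design$ei, , drop = FALSE]) %*% lambda)
  res <- design$y - beta[design$x1i] - M
  sigma2_e <- max(stats::var(res), 1e-8)
  s2l <- if (cfg$variant == "entropy") pmax(lambda^2, 1) else NULL
  param_state(beta, lambda, A, G, sigma2_e, s2l)
}

# re-orthonormalize columns in order, preserving direction of earlier ones
orthonormalize_cols <- function(M) {
  for (j in seq_len(ncol(M))) {
    if (j > 1L) {
      prev <- M[, seq_len(j - 1L), drop = FALSE]
      M[, j] <- M[, j] - prev %*% crossprod(prev, M[, j])
    }
    M[, j] <- M[, j] / sqrt(sum(M[, j]^2))
  }
  M
}

#' Run the Gibbs sampler for the Bayesian GGE model
#'
#' Systematic-scan Gibbs sampling of the linear-bilinear model: the block
#' effects, then for each bilinear component its singular value (truncated
#' normal, order constraint through the truncation bounds), under the
#' entropy variant its variance (inverse-gamma), and its genotype and
#' environment loadings (von Mises-Fisher in the orthogonality-corrected
#' subspace), and finally the residual variance (scaled inverse chi-square).
#' Freshly updated values are used within each scan.
#'
#' The von Mises-Fisher loading conditionals are exact only on a complete
#' balanced genotype x environment x block grid (otherwise the residual
#' quadratic form depends on the loading being sampled). Missing plot
#' records are therefore treated as latent variables and imputed from the
#' current fitted mean and residual variance at the top of every scan (data
#' augmentation), which keeps the grid balanced and every full conditional
#' exact. Reported log-likelihoods use the observed records only.
#'
#' @param design a [build_design()] object.
#' @param cfg a [model_config()].
#' @param plan an [mcmc_plan()].
#' @param seed integer seed; the chain is a deterministic function of it.
#' @return Object of class `"bgge_chain"`: list of draw matrices/arrays
#'   (`beta`, `lambda`, `alpha`, `gamma`, `sigma2_e`, `sigma2_lambda`,
#'   `loglik`), the `plan`, `cfg`, initial state and a re-orthonormalization
#'   counter.
#' @export
gibbs_run <- function(design, cfg, plan = mcmc_plan(), seed = 1L) {
  stopifnot(inherits(design, "met_design"), inherits(cfg, "bgge_config"))
  met <- design$met
  if (cfg$k > met$t)
    stop("k = ", cfg$k, " exceeds the maximal bilinear rank t = ", met$t,
         call. = FALSE)
  set.seed(seed)
  K <- cfg$k; n_obs <- met$n; v <- met$v; l <- met$l
  p_beta <- met$b * met$l
  entropy <- cfg$variant == "entropy"

  ## complete balanced grid (genotype fastest within each env:block cell);
  ## observed records map into it, the rest are latent and imputed each scan
  n <- p_beta * v
  gi <- rep(seq_len(v), p_beta)
  x1i <- rep(seq_len(p_beta), each = v)
  ei <- (x1i - 1L) %/% met$b + 1L
  pos_obs <- (design$x1i - 1L) * v + design$gi
  if (anyDuplicated(pos_obs))
    stop("duplicated (genotype, environment, block) records", call. = FALSE)
  obs <- logical(n); obs[pos_obs] <- TRUE
  counts1 <- tabulate(x1i, p_beta)

  st <- init_state(design, cfg)
  beta <- st$beta; lambda <- st$lambda; A <- st$A; G <- st$G
  sigma2_e <- st$sigma2_e; s2l <- st$sigma2_lambda
  Lmat <- A[gi, , drop = FALSE] * G[ei, , drop = FALSE]
  y <- beta[x1i] + as.vector(Lmat %*% lambda)   # init for latent records
  y[pos_obs] <- design$y

  n_keep <- plan$n_keep
  draws <- list(
    beta = matrix(NA_real_, n_keep, p_beta),
    lambda = matrix(NA_real_, n_keep, K),
    alpha = array(NA_real_, c(n_keep, v, K)),
    gamma = array(NA_real_, c(n_keep, l, K)),
    sigma2_e = numeric(n_keep),
    sigma2_lambda = if (entropy) matrix(NA_real_, n_keep, K) else NULL,
    loglik = numeric(n_keep)
  )
  n_reorth <- 0L
  kept <- 0L
  total <- plan$N

  lat <- !obs
  n_lat <- sum(lat)
  for (iter in seq_len(total)) {
    ## impute latent plot records from the current fit (data augmentation)
    M <- as.vector(Lmat %*% lambda)
    if (n_lat)
      y[lat] <- beta[x1i[lat]] + M[lat] +
        stats::rnorm(n_lat, 0, sqrt(sigma2_e))
    ## block-within-environment effects
    prec <- counts1 + sigma2_e / cfg$sigma2_beta
    bmean <- group_sum(y - M, x1i, p_beta) / prec
    beta <- bmean + stats::rnorm(p_beta, 0, sqrt(sigma2_e / prec))
    r0 <- y - beta[x1i]

    for (k in seq_len(K)) {
      ## singular value
      Lk <- Lmat[, k]
      Mk <- r0 - as.vector(Lmat %*% lambda) + lambda[k] * Lk
      s2lk <- if (entropy) max(s2l[k], cfg$sigma2_lambda_floor)
              else cfg$sigma2_lambda
      prk <- sum(Lk * Lk) + sigma2_e / s2lk
      lambda[k] <- rtruncnorm1(sum(Lk * Mk) / prk, sqrt(sigma2_e / prk),
                               lower = if (k < K) lambda[k + 1L] else 0,
                               upper = if (k > 1L) lambda[k - 1L] else Inf)
      ## its variance (entropy variant)
      if (entropy)
        s2l[k] <- rinv_gamma2(cfg$a + 1,
                              max(lambda[k]^2 + 2 * cfg$b_scale,
                                  cfg$sigma2_lambda_floor))
      ## genotype loading
      mu_raw <- group_sum(G[ei, k] * r0, gi, v)
      H <- if (K == 1L) diag(v) else orthonormal_complement(A[, -k, drop = FALSE])
      h <- as.vector(crossprod(H, mu_raw))
      hn <- sqrt(sum(h * h))
      kap <- if (hn > 0) hn * lambda[k] / sigma2_e else 0
      mu <- if (hn > 0) h / hn else c(1, rep(0, ncol(H) - 1L))
      A[, k] <- as.vector(H %*% rvmf(mu, kap))
      ## environment loading
      mu_raw <- group_sum(A[gi, k] * r0, ei, l)
      H <- if (K == 1L) diag(l) else orthonormal_complement(G[, -k, drop = FALSE])
      h <- as.vector(crossprod(H, mu_raw))
      hn <- sqrt(sum(h * h))
      kap <- if (hn > 0) hn * lambda[k] / sigma2_e else 0
      mu <- if (hn > 0) h / hn else c(1, rep(0, ncol(H) - 1L))
      G[, k] <- as.vector(H %*% rvmf(mu, kap))
      Lmat[, k] <- A[gi, k] * G[ei, k]
    }

    ## residual variance
    M <- as.vector(Lmat %*% lambda)
    sse <- sum((r0 - M)^2)
    sigma2_e <- sse / stats::rchisq(1, n)

    ## orthonormality drift guard
    if (iter %% 1000L == 0L && K > 1L) {
      if (max(abs(crossprod(A) - diag(K))) > 1e-8 ||
          max(abs(crossprod(G) - diag(K))) > 1e-8) {
        A <- orthonormalize_cols(A)
        G <- orthonormalize_cols(G)
        Lmat <- A[gi, , drop = FALSE] * G[ei, , drop = FALSE]
        n_reorth <- n_reorth + 1L
      }
    }

    if (iter > plan$burn_in && (iter - plan$burn_in) %% plan$thin == 0L &&
        kept < n_keep) {
      kept <- kept + 1L
      draws$beta[kept, ] <- beta
      draws$lambda[kept, ] <- lambda
      draws$alpha[kept, , ] <- A
      draws$gamma[kept, , ] <- G
      draws$sigma2_e[kept] <- sigma2_e
      if (entropy) draws$sigma2_lambda[kept, ] <- s2l
      res_obs <- (r0 - M)[pos_obs]
      ll <- -0.5 * n_obs * log(2 * pi * sigma2_e) -
        sum(res_obs^2) / (2 * sigma2_e)
      if (!is.finite(ll))
        stop("non-finite log-likelihood at iteration ", iter,
             "; sigma2_e = ", sigma2_e)
      draws$loglik[kept] <- ll
    }
  }
  if (kept < n_keep) {   # trim, should not happen with N = n_keep*thin + B
    idx <- seq_len(kept)
    draws$beta <- draws$beta[idx, , drop = FALSE]
    draws$lambda <- draws$lambda[idx, , drop = FALSE]
    draws$alpha <- draws$alpha[idx, , , drop = FALSE]
    draws$gamma <- draws$gamma[idx, , , drop = FALSE]
    draws$sigma2_e <- draws$sigma2_e[idx]
    if (entropy) draws$sigma2_lambda <- draws$sigma2_lambda[idx, , drop = FALSE]
    draws$loglik <- draws$loglik[idx]
  }
  structure(list(draws = draws, plan = plan, cfg = cfg, seed = seed,
                 n_reorth = n_reorth, init = st),
            class = "bgge_chain")
}

#' Fit the Bayesian GGE model to a multi-environment trial
#'
#' The model is `y = X1 beta + sum_k lambda_k diag(Z alpha_k) X2 gamma_k +
#' eps`: fixed block-within-environment effects plus a rank-`k` bilinear
#' term whose singular values are ordered and nonnegative and whose
#' genotype/environment loadings are orthonormal. `variant = "flat"` uses a
#' large fixed prior variance for the singular values (the non-shrinkage
#' Bayesian GGE); `variant = "entropy"` places a maximum-entropy
#' hierarchical prior on each singular-value variance, shrinking
#' weakly-supported components toward zero so that noise axes vanish without
#' a separate dimension-selection step.
#'
#' @param data a [met_table()], a [build_design()] object, or a data frame
#'   acceptable to [met_table()].
#' @param k number of bilinear components; defaults to the maximal rank `t`.
#' @param variant `"entropy"` (shrinkage, default) or `"flat"`.
#' @param plan an [mcmc_plan()].
#' @param seed integer seed.
#' @param ... further arguments passed to [model_config()].
#' @return Object of class `"bgge"`; see [gibbs_run()] for the chain
#'   layout. Supports `print`, `summary`, `coef`, `fitted`, `residuals`,
#'   `predict`, `plot` and `simulate` methods.
#' @examples
#' sim <- simulate_met(sim_config(v = 6, l = 3, b = 2), seed = 42)
#' fit <- bgge(sim$met, k = 2, variant = "entropy",
#'             plan = mcmc_plan(n_keep = 200, thin = 1, burn_in = 200))
#' fit
#' @export
bgge <- function(data, k = NULL, variant = c("entropy", "flat"),
                 plan = mcmc_plan(), seed = 1L, ...) {
  variant <- match.arg(variant)
  design <- if (inherits(data, "met_design")) data
            else if (inherits(data, "met_table")) build_design(data)
            else build_design(met_table(data))
  if (is.null(k)) k <- design$met$t
  cfg <- model_config(variant = variant, k = k, ...)
  chain <- gibbs_run(design, cfg, plan, seed)
  out <- c(chain, list(design = design, met = design$met,
                       call = match.call()))
  class(out) <- c("bgge", "bgge_chain")
  out
}

#' @export
print.bgge <- function(x, ...) {
  cat(sprintf("Bayesian GGE fit (%s prior), k = %d bilinear component(s)\n",
              if (x$cfg$variant == "entropy") "maximum-entropy shrinkage"
              else "flat", x$cfg$k))
  cat(sprintf("  data: %d records, %d genotypes x %d environments x %d blocks\n",
              x$met$n, x$met$v, x$met$l, x$met$b))
  cat(sprintf("  chain: %d retained draws (thin %d, burn-in %d)\n",
              nrow(x$draws$lambda), x$plan$thin, x$plan$burn_in))
  lam <- colMeans(x$draws$lambda)
  cat("  posterior mean singular values:\n   ",
      paste(sprintf("%.3g", lam), collapse = "  "), "\n")
  cat(sprintf("  posterior mean residual variance: %.3f\n",
              mean(x$draws$sigma2_e)))
  invisible(x)
}

#' @export
summary.bgge <- function(object, level = 0.95, ...) {
  summ <- function(x) {
    hpd <- hpd_interval(x, level)
    c(mean = mean(x), sd = stats::sd(x), lower = hpd[1], upper = hpd[2])
  }
  K <- object$cfg$k
  rows <- lapply(seq_len(K), function(k) summ(object$draws$lambda[, k]))
  tab <- do.call(rbind, rows)
  rownames(tab) <- paste0("lambda", seq_len(K))
  tab <- rbind(tab, sigma2_e = summ(object$draws$sigma2_e))
  if (!is.null(object$draws$sigma2_lambda)) {
    s2 <- do.call(rbind, lapply(seq_len(K), function(k)
      summ(object$draws$sigma2_lambda[, k])))
    rownames(s2) <- paste0("sigma2_lambda", seq_len(K))
    tab <- rbind(tab, s2)
  }
  out <- list(table = tab, level = level, cfg = object$cfg,
              n_draws = nrow(object$draws$lambda),
              share = variance_share(colMeans(object$draws$lambda)))
  class(out) <- "summary.bgge"
  out
}

#' @export
print.summary.bgge <- function(x, ...) {
  cat(sprintf("Posterior summaries (%d draws, %s prior):\n", x$n_draws,
              x$cfg$variant))
  print(round(x$table, 4))
  cat("\nVariance shares of bilinear components:",
      paste(sprintf("%.1f%%", 100 * x$share), collapse = "  "), "\n")
  invisible(x)
}

#' @export
coef.bgge <- function(object, ...) {
  al <- align_draws(object)
  K <- object$cfg$k
  list(beta = colMeans(object$draws$beta),
       lambda = colMeans(al$lambda),
       A = apply(al$alpha, c(2, 3), mean),
       G = apply(al$gamma, c(2, 3), mean),
       sigma2_e = mean(object$draws$sigma2_e))
}

# posterior mean of the bilinear cell surface (v x l), sign-invariant
posterior_mean_gge <- function(object) {
  nd <- nrow(object$draws$lambda)
  v <- object$met$v; l <- object$met$l
  acc <- matrix(0, v, l)
  for (d in seq_len(nd)) {
    Ad <- matrix(object$draws$alpha[d, , ], v)
    Gd <- matrix(object$draws$gamma[d, , ], l)
    acc <- acc + Ad %*% (object$draws$lambda[d, ] * t(Gd))
  }
  acc / nd
}

#' Predict cell means from a fitted Bayesian GGE model
#'
#' Returns the posterior mean of the fitted mean surface
#' `X1 beta + sum_k lambda_k alpha_k[g] gamma_k[e]` for each requested
#' record (Rao-Blackwellized over the retained draws). Records whose
#' genotype or environment was absent from the training data are flagged
#' `NA` with a warning.
#'
#' @param object a fitted [bgge()] model.
#' @param newdata optional data frame (or [met_table()]) with columns
#'   `genotype`, `environment`, `block`; defaults to the training records.
#' @param ... unused.
#' @return Numeric vector of predictions, one per row of `newdata`.
#' @export
predict.bgge <- function(object, newdata = NULL, ...) {
  met <- object$met
  if (is.null(newdata)) {
    gi <- object$design$gi; ei <- object$design$ei; x1i <- object$design$x1i
  } else {
    rec <- if (inherits(newdata, "met_table")) newdata$records else newdata
    gi <- match(as.character(rec$genotype), levels(met$records$genotype))
    ei <- match(as.character(rec$environment), levels(met$records$environment))
    bi <- match(as.character(rec$block), levels(met$records$block))
    if (anyNA(gi) || anyNA(ei) || anyNA(bi))
      warning("records with unseen genotype/environment/block levels are ",
              "not predictable and return NA")
    x1i <- (ei - 1L) * met$b + bi
  }
  mb <- colMeans(object$draws$beta)
  mgge <- posterior_mean_gge(object)
  out <- rep(NA_real_, length(gi))
  ok <- !is.na(gi) & !is.na(ei) & !is.na(x1i)
  out[ok] <- mb[x1i[ok]] + mgge[cbind(gi[ok], ei[ok])]
  out
}

#' @export
fitted.bgge <- function(object, ...) predict.bgge(object)

#' @export
residuals.bgge <- function(object, ...) {
  object$design$y - fitted.bgge(object)
}

#' Posterior predictive simulation from a fitted Bayesian GGE model
#'
#' For each replicate, one retained draw is selected at random and new
#' Gaussian responses are generated at its fitted mean and residual
#' variance.
#'
#' @param object a fitted [bgge()] model.
#' @param nsim number of replicate response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return `n x nsim` matrix of simulated responses for the training layout.
#' @export
simulate.bgge <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  nd <- nrow(object$draws$lambda)
  n <- object$met$n
  gi <- object$design$gi; ei <- object$design$ei; x1i <- object$design$x1i
  out <- matrix(NA_real_, n, nsim)
  for (j in seq_len(nsim)) {
    d <- sample.int(nd, 1L)
    Ad <- matrix(object$draws$alpha[d, , ], object$met$v)
    Gd <- matrix(object$draws$gamma[d, , ], object$met$l)
    bil <- Ad %*% (object$draws$lambda[d, ] * t(Gd))
    mu <- object$draws$beta[d, x1i] + bil[cbind(gi, ei)]
    out[, j] <- stats::rnorm(n, mu, sqrt(object$draws$sigma2_e[d]))
  }
  out
}
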