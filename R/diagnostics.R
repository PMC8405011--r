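#' Raftery-Lewis run-length diagnostic
#'
#' Estimates, from a pilot chain, the thinning, burn-in and total length
#' needed to estimate the `q`-quantile of a scalar parameter to within
#' `+/- r` with probability `s`. The series is dichotomized at its empirical
#' `q`-quantile; the thinning interval is increased until a first-order
#' two-state Markov chain is preferred over a second-order one (BIC), and
#' run lengths follow from the fitted transition probabilities. The
#' dependence factor `I = N_required / N_min` measures autocorrelation
#' inflation over an i.i.d. chain; values below 5 are conventionally
#' acceptable.
#'
#' @param x numeric vector of pilot draws.
#' @param q,r,s quantile of interest, target precision and probability.
#' @param eps convergence tolerance used in the burn-in formula.
#' @return List with `burn_in` (`M`), `N_required` (`M + N`), `N_min`,
#'   `I` and the selected `thin`.
#' @export
raftery_lewis <- function(x, q = 0.025, r = 0.005, s = 0.95, eps = 0.001) {
  phi <- stats::qnorm(0.5 * (1 + s))
  n_min <- ceiling(phi^2 * q * (1 - q) / r^2)
  n <- length(x)
  if (n < n_min)
    stop("pilot too short: ", n, " draws, need at least ", n_min,
         call. = FALSE)
  z <- as.integer(x <= stats::quantile(x, q, names = FALSE))

  kthin <- 0L
  repeat {
    kthin <- kthin + 1L
    zt <- z[seq(1L, n, by = kthin)]
    nt <- length(zt)
    if (nt < 4L) break
    # second-order vs first-order Markov comparison via BIC on triplets
    trip <- table(factor(zt[1:(nt - 2)], levels = 0:1),
                  factor(zt[2:(nt - 1)], levels = 0:1),
                  factor(zt[3:nt],       levels = 0:1))
    g2 <- 0
    for (i1 in 1:2) for (i2 in 1:2) for (i3 in 1:2) {
      obs <- trip[i1, i2, i3]
      if (obs == 0) next
      expd <- sum(trip[i1, i2, ]) * sum(trip[, i2, i3]) / sum(trip[, i2, ])
      g2 <- g2 + 2 * obs * log(obs / expd)
    }
    bic <- g2 - 2 * log(nt - 2)
    if (bic < 0) break
  }
  zt <- z[seq(1L, n, by = kthin)]
  nt <- length(zt)
  from <- zt[1:(nt - 1)]; to <- zt[2:nt]
  alpha <- sum(from == 0 & to == 1) / max(sum(from == 0), 1L)  # 0 -> 1
  beta  <- sum(from == 1 & to == 0) / max(sum(from == 1), 1L)  # 1 -> 0
  alpha <- min(max(alpha, 1e-8), 1 - 1e-8)
  beta  <- min(max(beta,  1e-8), 1 - 1e-8)
  m <- ceiling(log(eps * (alpha + beta) / max(alpha, beta)) /
                 log(abs(1 - alpha - beta)))
  M <- m * kthin
  nreq <- ceiling((2 - alpha - beta) * alpha * beta * phi^2 /
                    ((alpha + beta)^3 * r^2))
  N <- nreq * kthin
  list(burn_in = M, N_required = M + N, N_min = n_min,
       I = (M + N) / n_min, thin = kthin)
}

# asymptotic Cramer-von Mises distribution function. The four-term Bessel
# series is accurate on (0, ~1.5] but decays spuriously for larger q, where
# the true upper-tail mass is below 2e-4; clamp there so huge statistics
# keep p-values near zero.
pcramer <- function(q) {
  if (q <= 0) return(0)
  if (q > 1.5) return(1)
  acc <- 0
  for (k in 0:3) {
    z <- (4 * k + 1)^2 / (16 * q)
    acc <- acc + choose(-0.5, k) * (-1)^k * sqrt(4 * k + 1) *
      exp(-z) * besselK(z, 0.25)
  }
  acc / (pi * sqrt(q))
}

# spectral density at frequency zero via an AR fit
spectrum0 <- function(x) {
  x <- as.numeric(x)
  if (stats::var(x) == 0) return(0)
  fit <- stats::ar(x, aic = TRUE)
  if (length(fit$ar) == 0) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Heidelberger-Welch stationarity and halfwidth diagnostic
#'
#' The stationarity test applies a Cramer-von Mises statistic (with the
#' long-run variance estimated by the spectral density at zero from the
#' second half of the chain) to the full chain, then iteratively discards
#' 10% from the front until the test passes or half the chain is gone. The
#' halfwidth test checks whether the `(1-alpha)` confidence halfwidth of the
#' retained-segment mean is below `eps` times the magnitude of the mean.
#'
#' @param x numeric vector of draws (length >= 100).
#' @param alpha significance level of the stationarity test.
#' @param eps relative halfwidth tolerance.
#' @return List with `stationarity` (pass flag), `kept_fraction`, `start`
#'   (first retained index), `pvalue`, `mean`, `halfwidth`,
#'   `halfwidth_pass`.
#' @export
heidelberger_welch <- function(x, alpha = 0.05, eps = 0.1) {
  n <- length(x)
  if (n < 100L) stop("need at least 100 draws", call. = FALSE)
  if (stats::var(x) == 0) {
    return(list(stationarity = TRUE, kept_fraction = 1, start = 1L,
                pvalue = 1, mean = mean(x), halfwidth = 0,
                halfwidth_pass = TRUE))
  }
  s0 <- spectrum0(x[(n %/% 2 + 1L):n])
  passed <- FALSE; start <- 1L; pval <- NA_real_
  for (frac in seq(0, 0.5, by = 0.1)) {
    start <- floor(frac * n) + 1L
    seg <- x[start:n]
    m <- length(seg)
    csum <- cumsum(seg)
    bridge <- (csum - seq_len(m) * mean(seg)) / sqrt(m * s0)
    cvm <- sum(bridge^2) / m
    pval <- 1 - pcramer(cvm)
    if (pval > alpha) { passed <- TRUE; break }
  }
  seg <- x[start:n]
  s0k <- spectrum0(seg)
  hw <- stats::qnorm(1 - alpha / 2) * sqrt(s0k / length(seg))
  mu <- mean(seg)
  list(stationarity = passed, kept_fraction = length(seg) / n,
       start = start, pvalue = pval, mean = mu, halfwidth = hw,
       halfwidth_pass = is.finite(hw) && abs(mu) > 0 && hw / abs(mu) < eps)
}

#' Effective sample size
#'
#' Initial-monotone-sequence estimator: the integrated autocorrelation time
#' is `1 + 2 * sum(rho_j)` with the sum truncated where consecutive
#' autocorrelation pairs stop being positive and monotone nonincreasing.
#' Capped at the series length (an antithetic chain would otherwise report
#' more effective than actual draws).
#'
#' @param x numeric vector of draws (length >= 10).
#' @return Estimated effective sample size, in `(0, length(x)]`.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 10L) stop("need at least 10 draws", call. = FALSE)
  if (stats::var(x) == 0) return(n)
  maxlag <- min(n - 1L, 2000L)
  rho <- as.vector(stats::acf(x, lag.max = maxlag, plot = FALSE,
                              demean = TRUE)$acf)[-1]
  npair <- length(rho) %/% 2L
  gam <- rho[2 * seq_len(npair) - 1L] + rho[2 * seq_len(npair)]
  tau <- 1
  prev <- Inf
  for (i in seq_len(npair)) {
    g <- min(gam[i], prev)        # enforce monotone nonincreasing
    if (g <= 0) break
    tau <- tau + 2 * g
    prev <- g
  }
  min(n, n / tau)
}

#' Plan a final chain from pilot diagnostics
#'
#' Applies the run-length rule `N = n_keep * J + B`: the thinning `J` is the
#' largest Raftery-Lewis dependence factor (rounded up) over the monitored
#' scalars, and the burn-in `B` is the largest suggested burn-in, floored at
#' `min_burn_in`.
#'
#' @param pilot_results list of [raftery_lewis()] outputs, one per
#'   monitored scalar.
#' @param n_keep retained draws desired.
#' @param min_burn_in lower bound on the burn-in.
#' @return An [mcmc_plan()].
#' @export
plan_run <- function(pilot_results, n_keep = 4000L, min_burn_in = 10000L) {
  if (!length(pilot_results)) stop("no pilot results", call. = FALSE)
  J <- max(1L, ceiling(max(vapply(pilot_results, `[[`, numeric(1), "I"))))
  B <- max(min_burn_in, max(vapply(pilot_results, `[[`, numeric(1),
                                   "burn_in")))
  mcmc_plan(n_keep = n_keep, thin = J, burn_in = B)
}

#' Convergence report for a fitted chain
#'
#' Runs Raftery-Lewis, Heidelberger-Welch and effective-sample-size
#' diagnostics on the monitored scalars of a fit: every singular value, the
#' residual variance and (entropy variant) every singular-value variance.
#'
#' @param fit a fitted [bgge()] model.
#' @param q,r,s Raftery-Lewis settings.
#' @param alpha Heidelberger-Welch significance level.
#' @param I_max acceptance cap on the dependence factor.
#' @return Data frame with one row per monitored scalar and an attribute
#'   `pass` (all dependence factors below `I_max`, all stationarity tests
#'   passed, all effective sizes above 0).
#' @export
diagnose <- function(fit, q = 0.025, r = 0.005, s = 0.95, alpha = 0.05,
                     I_max = 5) {
  mons <- list()
  K <- fit$cfg$k
  for (k in seq_len(K)) mons[[paste0("lambda", k)]] <- fit$draws$lambda[, k]
  mons[["sigma2_e"]] <- fit$draws$sigma2_e
  if (!is.null(fit$draws$sigma2_lambda))
    for (k in seq_len(K))
      mons[[paste0("sigma2_lambda", k)]] <- fit$draws$sigma2_lambda[, k]
  rows <- lapply(names(mons), function(nm) {
    xx <- mons[[nm]]
    rl <- tryCatch(raftery_lewis(xx, q, r, s),
                   error = function(e) list(burn_in = NA, N_required = NA,
                                            N_min = NA, I = NA, thin = NA))
    hw <- heidelberger_welch(xx, alpha)
    data.frame(parameter = nm, I = rl$I, rl_burn_in = rl$burn_in,
               ess = ess(xx), hw_stationary = hw$stationarity,
               hw_pvalue = hw$pvalue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "pass") <- all(is.na(out$I) | out$I < I_max) &&
    all(out$hw_stationary)
  out
}
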