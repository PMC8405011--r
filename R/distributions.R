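#' Uniform draw on the unit sphere
#'
#' @param m ambient dimension (sphere lives in R^m).
#' @return Unit vector of length `m`.
#' @keywords internal
runit_sphere <- function(m) {
  repeat {
    x <- stats::rnorm(m)
    nrm <- sqrt(sum(x * x))
    if (nrm > 0) return(x / nrm)
  }
}

#' Draw from a von Mises-Fisher distribution
#'
#' Rejection sampler for the vMF distribution on the unit sphere in `R^m`
#' (Wood's envelope for the cosine of the angle to the mean direction, a
#' Householder reflection to rotate the pole onto `mu`). `kappa = 0` gives
#' the uniform distribution on the sphere; `m = 1` reduces to a two-point
#' distribution on {-1, +1}.
#'
#' @param mu mean direction (unit vector, length `m`).
#' @param kappa concentration parameter, `>= 0`.
#' @return Unit vector of length `m`.
#' @export
rvmf <- function(mu, kappa) {
  if (kappa < 0) stop("kappa must be nonnegative", call. = FALSE)
  m <- length(mu)
  if (m == 1L) {
    # sphere in R^1 is {-1, +1}; P(x = s) proportional to exp(kappa * mu * s)
    p <- 1 / (1 + exp(-2 * kappa * mu))
    return(if (stats::runif(1) < p) 1 else -1)
  }
  if (kappa < 1e-12) return(runit_sphere(m))
  d <- m - 1
  if (kappa > 1e6) {
    # Wood's envelope loses precision when the cosine concentrates within
    # ~1e-6 of 1; use the exact large-kappa limit kappa*(1 - w) -> Gamma(d/2)
    w <- max(-1, 1 - stats::rgamma(1, d / 2, 1) / kappa)
  } else {
    b <- d / (sqrt(4 * kappa^2 + d^2) + 2 * kappa)
    x0 <- (1 - b) / (1 + b)
    cc <- kappa * x0 + d * log(1 - x0^2)
    repeat {
      z <- stats::rbeta(1, d / 2, d / 2)
      w <- (1 - (1 + b) * z) / (1 - (1 - b) * z)
      if (kappa * w + d * log(1 - x0 * w) - cc >= log(stats::runif(1))) break
    }
  }
  tang <- if (d == 1L) sample(c(-1, 1), 1L) else runit_sphere(d)
  x <- c(sqrt(max(0, 1 - w^2)) * tang, w)    # pole at e_m
  u <- c(rep(0, m - 1), 1) - mu              # reflect e_m onto mu
  un <- sqrt(sum(u * u))
  if (un < 1e-12) return(x)
  u <- u / un
  x - 2 * u * sum(u * x)
}

#' Orthonormal basis of the complement of a set of orthonormal columns
#'
#' @param V matrix with orthonormal columns (possibly zero columns).
#' @param m ambient dimension; defaults to `nrow(V)`.
#' @return `m x (m - ncol(V))` matrix `H` with `t(H) %*% H = I` and
#'   `t(H) %*% V = 0`.
#' @export
orthonormal_complement <- function(V, m = nrow(V)) {
  if (is.null(V) || length(V) == 0L || NCOL(V) == 0L) return(diag(m))
  V <- as.matrix(V)
  stopifnot(nrow(V) == m)
  qrv <- qr(V)
  if (qrv$rank < ncol(V))
    stop("columns of V are linearly dependent", call. = FALSE)
  gram <- crossprod(V)
  if (max(abs(gram - diag(ncol(V)))) > 1e-6)
    stop("columns of V are not orthonormal", call. = FALSE)
  Q <- qr.Q(qrv, complete = TRUE)
  Q[, (ncol(V) + 1L):m, drop = FALSE]
}

#' Draw from a truncated normal distribution
#'
#' Inverse-CDF sampling with log-space tail handling, stable even when the
#' truncation interval sits many standard deviations into a tail.
#'
#' @param mean,sd location and scale of the parent normal.
#' @param lower,upper truncation bounds (`-Inf`/`Inf` allowed;
#'   `lower <= upper` required).
#' @return One draw from N(mean, sd^2) restricted to `[lower, upper]`.
#' @export
rtruncnorm1 <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (lower > upper) stop("lower > upper in truncated normal", call. = FALSE)
  if (lower == upper) return(lower)
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  u <- stats::runif(1)
  z <- if (a >= 0) {
    # work in the upper tail on the log scale
    la <- stats::pnorm(a, lower.tail = FALSE, log.p = TRUE)
    lb <- stats::pnorm(b, lower.tail = FALSE, log.p = TRUE)
    lt <- la + log1p(-u * (1 - exp(lb - la)))
    stats::qnorm(lt, lower.tail = FALSE, log.p = TRUE)
  } else if (b <= 0) {
    la <- stats::pnorm(a, log.p = TRUE)
    lb <- stats::pnorm(b, log.p = TRUE)
    lt <- lb + log1p(-u * (1 - exp(la - lb)))
    stats::qnorm(lt, log.p = TRUE)
  } else {
    pa <- stats::pnorm(a)
    pb <- stats::pnorm(b)
    stats::qnorm(pa + u * (pb - pa))
  }
  # guard against round-off pushing the draw just outside the interval
  mean + sd * min(max(z, a), b)
}

#' Draw from a scaled inverse chi-square distribution
#'
#' Parameterized by degrees of freedom `df` and scale `scale`, so that
#' `df * scale / X ~ chi^2_df`.
#'
#' @param df degrees of freedom.
#' @param scale scale parameter.
#' @return One positive draw.
#' @export
rscaled_inv_chisq <- function(df, scale) {
  df * scale / stats::rchisq(1, df)
}

#' Draw from the inverse-gamma family used for singular-value variances
#'
#' The density is proportional to `x^-(shape + 1) * exp(-scale2 / (2 x))`,
#' the form that arises as the full conditional of a singular-value variance
#' under the maximum-entropy hierarchical prior; equivalently
#' `scale2 / X ~ chi^2_(2 * shape)`.
#'
#' @param shape shape parameter.
#' @param scale2 scale parameter (enters the exponent as `scale2 / (2 x)`).
#' @return One positive draw.
#' @export
rinv_gamma2 <- function(shape, scale2) {
  scale2 / stats::rchisq(1, 2 * shape)
}
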