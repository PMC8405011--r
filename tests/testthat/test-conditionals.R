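# Build a consistent toy state from the frequentist decomposition of a
# small balanced trial, for conditional-distribution oracles.
toy_state <- function(K = 2, noise_sd = 0.5, seed = 42) {
  met <- toy_met(noise_sd = noise_sd, seed = seed)
  design <- build_design(met)
  sv <- svd_gge(center_gge_matrix(met))
  beta <- tapply(design$y, design$x1i, mean)
  state <- param_state(beta = as.numeric(beta),
                       lambda = sv$lambda[seq_len(K)],
                       A = sv$A[, seq_len(K), drop = FALSE],
                       G = sv$G[, seq_len(K), drop = FALSE],
                       sigma2_e = 0.3,
                       sigma2_lambda = rep(4, K))
  list(met = met, design = design, state = state)
}

test_that("model_config validates arguments", {
  cfg <- model_config("entropy", k = 3)
  expect_equal(cfg$a, 1)
  expect_equal(cfg$b_scale, 0)
  expect_equal(cfg$sigma2_lambda, 1e8)
  expect_error(model_config("entropy", k = 0), "at least 1")
  expect_error(model_config("bogus", k = 1))
})

test_that("cond_beta matches the dense matrix-normal oracle", {
  ts <- toy_state()
  cfg <- model_config("flat", k = 2, sigma2_beta = 7)
  spec <- cond_beta(ts$state, ts$design, cfg)
  X1 <- ts$design$X1
  M <- as.vector((ts$state$A[ts$design$gi, ] *
                  ts$state$G[ts$design$ei, ]) %*% ts$state$lambda)
  prec <- crossprod(X1) + diag(ts$state$sigma2_e / 7, ncol(X1))
  mean_or <- solve(prec, crossprod(X1, ts$design$y - M))
  var_or <- diag(solve(prec)) * ts$state$sigma2_e
  expect_equal(spec$mean, as.numeric(mean_or), tolerance = 1e-10)
  expect_equal(spec$var, var_or, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("cond_beta with a diffuse prior returns cell residual means", {
  ts <- toy_state()
  cfg <- model_config("flat", k = 2, sigma2_beta = 1e12)
  spec <- cond_beta(ts$state, ts$design, cfg)
  M <- as.vector((ts$state$A[ts$design$gi, ] *
                  ts$state$G[ts$design$ei, ]) %*% ts$state$lambda)
  means <- tapply(ts$design$y - M, ts$design$x1i, mean)
  expect_equal(spec$mean, as.numeric(means), tolerance = 1e-6)
})

test_that("cond_lambda is proportional to the true conditional density", {
  ts <- toy_state()
  cfg <- model_config("flat", k = 2, sigma2_lambda = 25)
  k <- 1L
  spec <- cond_lambda(ts$state, ts$design, cfg, k)
  # brute-force log conditional on a grid: Gaussian likelihood in lambda_k
  # times the half-normal prior
  Lk <- ts$state$A[ts$design$gi, k] * ts$state$G[ts$design$ei, k]
  resid0 <- ts$design$y - ts$state$beta[ts$design$x1i] -
    ts$state$lambda[2] *
      ts$state$A[ts$design$gi, 2] * ts$state$G[ts$design$ei, 2]
  grid <- seq(spec$lower + 0.01, spec$lower + 2, length.out = 25)
  logf <- vapply(grid, function(lam)
    -sum((resid0 - lam * Lk)^2) / (2 * ts$state$sigma2_e) -
      lam^2 / (2 * 25), numeric(1))
  logg <- dnorm(grid, spec$location, sqrt(spec$scale2), log = TRUE)
  # proportionality: difference constant over the grid
  expect_lt(diff(range(logf - logg)), 1e-8)
})

test_that("cond_lambda truncation enforces the order constraint", {
  ts <- toy_state(K = 2)
  cfg <- model_config("flat", k = 2)
  s1 <- cond_lambda(ts$state, ts$design, cfg, 1L)
  s2 <- cond_lambda(ts$state, ts$design, cfg, 2L)
  expect_equal(s1$lower, ts$state$lambda[2])
  expect_equal(s1$upper, Inf)
  expect_equal(s2$lower, 0)
  expect_equal(s2$upper, ts$state$lambda[1])
})

test_that("balanced orthonormal loadings give regressor norm b", {
  ts <- toy_state()
  for (k in 1:2) {
    Lk <- ts$state$A[ts$design$gi, k] * ts$state$G[ts$design$ei, k]
    expect_equal(sum(Lk^2), ts$met$b, tolerance = 1e-10)
  }
})

test_that("entropy variant with huge frozen variance equals flat", {
  ts <- toy_state()
  flat <- model_config("flat", k = 2, sigma2_lambda = 1e8)
  ent <- model_config("entropy", k = 2)
  st <- ts$state
  st$sigma2_lambda <- rep(1e8, 2)
  sf <- cond_lambda(ts$state, ts$design, flat, 1L)
  se <- cond_lambda(st, ts$design, ent, 1L)
  expect_equal(sf$location, se$location, tolerance = 1e-12)
  expect_equal(sf$scale2, se$scale2, tolerance = 1e-12)
})

test_that("cond_sigma_lambda returns GI(a + 1, lambda^2 + 2b)", {
  ts <- toy_state()
  cfg <- model_config("entropy", k = 2, a = 1, b_scale = 0)
  spec <- cond_sigma_lambda(ts$state, cfg, 1L)
  expect_equal(spec$shape, 2)
  expect_equal(spec$scale2, ts$state$lambda[1]^2)
  cfgb <- model_config("entropy", k = 2, a = 3, b_scale = 0.5)
  specb <- cond_sigma_lambda(ts$state, cfgb, 2L)
  expect_equal(specb$shape, 4)
  expect_equal(specb$scale2, ts$state$lambda[2]^2 + 1)
  expect_error(cond_sigma_lambda(ts$state, model_config("flat", k = 2), 1L),
               "entropy")
})

test_that("collapsed singular value hits the variance floor, not zero", {
  ts <- toy_state()
  st <- ts$state
  st$lambda[2] <- 0
  cfg <- model_config("entropy", k = 2)
  spec <- cond_sigma_lambda(st, cfg, 2L)
  expect_equal(spec$scale2, cfg$sigma2_lambda_floor)
  expect_gt(spec$scale2, 0)
})

test_that("cond_vector matches the exponential-family linear form", {
  ts <- toy_state()
  cfg <- model_config("flat", k = 2)
  for (side in c("genotypic", "environmental")) {
    k <- 1L
    spec <- cond_vector(ts$state, ts$design, cfg, k, side)
    resid <- ts$design$y - ts$state$beta[ts$design$x1i]
    # the true log conditional at loading vector u is
    # (lambda_k / sigma2_e) * u' w, with w the residual-weighted partner sums
    if (side == "genotypic") {
      w <- as.numeric(rowsum(ts$state$G[ts$design$ei, k] * resid,
                             ts$design$gi))
      other <- ts$state$A[, 2, drop = FALSE]
    } else {
      w <- as.numeric(rowsum(ts$state$A[ts$design$gi, k] * resid,
                             ts$design$ei))
      other <- ts$state$G[, 2, drop = FALSE]
    }
    # the subspace basis is orthogonal to the other same-side loading
    expect_equal(crossprod(other, spec$H),
                 matrix(0, 1, spec$m), tolerance = 1e-10,
                 ignore_attr = TRUE)
    # for any z on the subspace sphere, the vMF exponent kappa * mu'z must
    # equal the model's linear form at u = H z
    set.seed(5)
    for (i in 1:5) {
      z <- runit_sphere(spec$m)
      u <- as.numeric(spec$H %*% z)
      lhs <- spec$kappa * sum(spec$mu * z)
      rhs <- ts$state$lambda[k] / ts$state$sigma2_e * sum(u * w)
      expect_equal(lhs, rhs, tolerance = 1e-10)
    }
  }
})

test_that("cond_vector subspace dimension is full minus K - 1", {
  ts <- toy_state(K = 2)
  cfg <- model_config("flat", k = 2)
  expect_equal(cond_vector(ts$state, ts$design, cfg, 1L, "genotypic")$m,
               ts$met$v - 1L)
  expect_equal(cond_vector(ts$state, ts$design, cfg, 2L, "environmental")$m,
               ts$met$l - 1L)
})

test_that("cond_sigma_e returns df = n and scale = SSE / n", {
  ts <- toy_state()
  spec <- cond_sigma_e(ts$state, ts$design)
  fit <- ts$state$beta[ts$design$x1i] +
    as.vector((ts$state$A[ts$design$gi, ] *
               ts$state$G[ts$design$ei, ]) %*% ts$state$lambda)
  expect_equal(spec$df, ts$met$n)
  expect_equal(spec$scale, sum((ts$design$y - fit)^2) / ts$met$n,
               tolerance = 1e-12)
})
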