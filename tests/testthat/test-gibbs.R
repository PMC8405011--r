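test_that("mcmc_plan computes the total chain length", {
  plan <- mcmc_plan(n_keep = 100, thin = 5, burn_in = 200)
  expect_equal(plan$N, 700L)
  expect_error(mcmc_plan(thin = 0), "thin")
})

test_that("loglik matches a hand-computed Gaussian log density", {
  met <- toy_met(noise_sd = 0.4)
  design <- build_design(met)
  sv <- svd_gge(center_gge_matrix(met))
  st <- param_state(beta = rep(10, 6), lambda = sv$lambda[1:2],
                    A = sv$A[, 1:2], G = sv$G[, 1:2], sigma2_e = 2)
  mu <- st$beta[design$x1i] +
    as.vector((sv$A[design$gi, 1:2] * sv$G[design$ei, 1:2]) %*% sv$lambda[1:2])
  expect_equal(loglik(st, design),
               sum(dnorm(design$y, mu, sqrt(2), log = TRUE)),
               tolerance = 1e-10)
  st$sigma2_e <- -1
  expect_error(loglik(st, design), "positive")
})

test_that("chains are deterministic functions of the seed", {
  met <- toy_met(noise_sd = 0.5)
  plan <- mcmc_plan(n_keep = 50, thin = 1, burn_in = 50)
  f1 <- bgge(met, k = 2, variant = "entropy", plan = plan, seed = 9)
  f2 <- bgge(met, k = 2, variant = "entropy", plan = plan, seed = 9)
  f3 <- bgge(met, k = 2, variant = "entropy", plan = plan, seed = 10)
  expect_identical(f1$draws, f2$draws)
  expect_false(identical(f1$draws$lambda, f3$draws$lambda))
})

test_that("every retained draw satisfies the model constraints", {
  fit <- bgge(toy_met(noise_sd = 0.5), k = 3, variant = "entropy",
              plan = mcmc_plan(n_keep = 200, thin = 1, burn_in = 200),
              seed = 2)
  lam <- fit$draws$lambda
  expect_true(all(lam >= 0))
  expect_true(all(lam[, 1] >= lam[, 2] & lam[, 2] >= lam[, 3]))
  expect_true(all(fit$draws$sigma2_e > 0))
  for (d in c(1, 50, 200)) {
    Ad <- matrix(fit$draws$alpha[d, , ], 4)
    Gd <- matrix(fit$draws$gamma[d, , ], 3)
    expect_equal(crossprod(Ad), diag(3), tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(crossprod(Gd), diag(3), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("flat fit concentrates on the frequentist SVD as noise vanishes", {
  met <- toy_met(noise_sd = 1e-3, seed = 8)
  sv <- svd_gge(center_gge_matrix(met))
  fit <- bgge(met, k = 2, variant = "flat",
              plan = mcmc_plan(n_keep = 300, thin = 1, burn_in = 300),
              seed = 3)
  lam_hat <- colMeans(fit$draws$lambda)
  expect_equal(lam_hat[1], sv$lambda[1], tolerance = 0.01)
  # posterior sd shrinks with the noise
  expect_lt(sd(fit$draws$lambda[, 1]), 0.05)
})

test_that("residual variance is recovered on simulated data", {
  fit <- shared_fit()
  s2 <- mean(fit$draws$sigma2_e)
  # generator uses sigma2_eps = 6; n = 420 so the posterior is tight, but
  # discarded bilinear noise axes inflate the estimate slightly
  expect_gt(s2, 4.5)
  expect_lt(s2, 8.5)
})

test_that("entropy prior collapses noise axes on simulated data", {
  fit <- shared_fit()
  lam <- colMeans(fit$draws$lambda)
  # two structured axes survive, the rest collapse by orders of magnitude
  expect_gt(lam[2] / lam[3], 100)
})

test_that("bgge accepts data frames, met tables and designs alike", {
  rec <- toy_records(noise_sd = 0.5); names(rec)[4] <- "response"
  met <- met_table(rec)
  plan <- mcmc_plan(n_keep = 30, thin = 1, burn_in = 30)
  f_df <- bgge(rec, k = 1, plan = plan, seed = 4)
  f_met <- bgge(met, k = 1, plan = plan, seed = 4)
  f_des <- bgge(build_design(met), k = 1, plan = plan, seed = 4)
  expect_identical(f_df$draws, f_met$draws)
  expect_identical(f_met$draws, f_des$draws)
  # k defaults to t
  f_def <- bgge(met, plan = plan, seed = 4)
  expect_equal(f_def$cfg$k, met$t)
  expect_error(bgge(met, k = met$t + 1, plan = plan), "exceeds the maximal")
})

test_that("standard S3 methods work on a fitted model", {
  fit <- bgge(toy_met(noise_sd = 0.5), k = 2,
              plan = mcmc_plan(n_keep = 100, thin = 1, burn_in = 100),
              seed = 6)
  expect_output(print(fit), "Bayesian GGE fit")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.bgge")
  expect_output(print(sm), "Posterior summaries")
  expect_true(all(c("lambda1", "sigma2_e") %in% rownames(sm$table)))
  cf <- coef(fit)
  expect_named(cf, c("beta", "lambda", "A", "G", "sigma2_e"))
  expect_equal(dim(cf$A), c(4L, 2L))
  ft <- fitted(fit)
  expect_length(ft, 24L)
  expect_equal(residuals(fit), fit$design$y - ft)
  # in-sample fit should explain most of the signal
  expect_gt(cor(ft, fit$design$y), 0.95)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(24L, 3L))
})

test_that("predict handles new data and flags unseen levels", {
  fit <- bgge(toy_met(noise_sd = 0.5), k = 2,
              plan = mcmc_plan(n_keep = 100, thin = 1, burn_in = 100),
              seed = 6)
  nd <- data.frame(genotype = c("G1", "G9"), environment = c("E2", "E1"),
                   block = c("B1", "B1"))
  expect_warning(p <- predict(fit, nd), "unseen")
  expect_false(is.na(p[1]))
  expect_true(is.na(p[2]))
  expect_equal(predict(fit)[1], fitted(fit)[1])
})

test_that("unbalanced data (missing cells) still fit", {
  rec <- toy_records(v = 5, l = 4, b = 2, noise_sd = 0.5)
  names(rec)[4] <- "response"
  rec <- rec[!(rec$genotype == "G2" & rec$environment == "E3"), ]
  fit <- bgge(met_table(rec), k = 2,
              plan = mcmc_plan(n_keep = 100, thin = 1, burn_in = 100),
              seed = 13)
  expect_true(all(is.finite(fit$draws$lambda)))
  # predictions exist for the never-observed cell too
  nd <- data.frame(genotype = "G2", environment = "E3", block = "B1")
  expect_false(is.na(predict(fit, nd)))
})
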