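test_that("hpd_interval matches the normal-theory interval", {
  set.seed(1)
  x <- rnorm(50000, mean = 3, sd = 2)
  h <- hpd_interval(x, 0.95)
  expect_equal(h[1], 3 - 1.96 * 2, tolerance = 0.05)
  expect_equal(h[2], 3 + 1.96 * 2, tolerance = 0.05)
  # for a skewed sample the HPD is shorter than the equal-tail interval
  y <- rexp(50000)
  hy <- hpd_interval(y, 0.9)
  et <- quantile(y, c(0.05, 0.95), names = FALSE)
  expect_lt(diff(hy), et[2] - et[1])
  expect_equal(hy[1], 0, tolerance = 0.01)  # mode of the exponential
})

test_that("hpd_interval contains approximately the nominal mass", {
  set.seed(2)
  x <- rgamma(20000, shape = 3)
  h <- hpd_interval(x, 0.9)
  expect_equal(mean(x >= h[1] & x <= h[2]), 0.9, tolerance = 0.005)
})

test_that("point_in_convex classifies points against a polygon", {
  sq <- rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))
  expect_true(bgge:::point_in_convex(c(0, 0), sq))
  expect_true(bgge:::point_in_convex(c(1, 0), sq))     # boundary counts
  expect_false(bgge:::point_in_convex(c(2, 0), sq))
  expect_false(bgge:::point_in_convex(c(0, 0), sq[1:2, , drop = FALSE]))
})

test_that("credible_region keeps the nominal fraction of draws", {
  set.seed(3)
  pts <- cbind(rnorm(5000, 1), rnorm(5000, -1, 0.5))
  cr <- credible_region(pts, 0.95)
  expect_s3_class(cr, "credible_region")
  expect_false(cr$degenerate)
  inside <- mean(apply(pts, 1, bgge:::point_in_convex, poly = cr$boundary))
  expect_gte(inside, 0.945)
  expect_lte(inside, 0.965)
  # origin is ~2 sd away in both axes: region of a tight cloud excludes it
  tight <- cbind(rnorm(1000, 5, 0.1), rnorm(1000, 5, 0.1))
  expect_false(credible_region(tight)$contains_origin)
  centered <- cbind(rnorm(1000, 0, 1), rnorm(1000, 0, 1))
  expect_true(credible_region(centered)$contains_origin)
  expect_error(credible_region(pts[1:10, ]), "at least 100")
})

test_that("credible_region falls back to a box for degenerate clouds", {
  pts <- cbind(rnorm(500), rep(2, 500))    # zero variance on axis 2
  cr <- credible_region(pts)
  expect_true(cr$degenerate)
  expect_equal(nrow(cr$boundary), 4L)
  expect_false(cr$contains_origin)
})

test_that("align_draws removes reflection switching without changing fits", {
  fit <- shared_fit()
  al <- align_draws(fit)
  # after alignment every draw agrees in sign with the reference
  for (k in 1:2) {
    agree <- al$alpha[, , k] %*% al$Aref[, k] + al$gamma[, , k] %*% al$Gref[, k]
    expect_true(all(agree >= 0))
  }
  # a joint flip leaves the bilinear surface invariant: check one draw
  d <- 1L
  A1 <- matrix(fit$draws$alpha[d, , ], fit$met$v)
  G1 <- matrix(fit$draws$gamma[d, , ], fit$met$l)
  A2 <- matrix(al$alpha[d, , ], fit$met$v)
  G2 <- matrix(al$gamma[d, , ], fit$met$l)
  lam <- fit$draws$lambda[d, ]
  expect_equal(A1 %*% (lam * t(G1)), A2 %*% (lam * t(G2)),
               tolerance = 1e-10)
})

test_that("align_draws collapses artificial sign switching", {
  fit <- shared_fit()
  flipped <- fit
  nd <- nrow(fit$draws$lambda)
  half <- seq_len(nd %/% 2)
  flipped$draws$alpha[half, , 1] <- -flipped$draws$alpha[half, , 1]
  flipped$draws$gamma[half, , 1] <- -flipped$draws$gamma[half, , 1]
  al0 <- align_draws(fit)
  al1 <- align_draws(flipped)
  # alignment undoes the manual flips: axis-1 loadings agree again
  expect_equal(al1$alpha[, , 1], al0$alpha[, , 1], tolerance = 1e-10)
  expect_equal(al1$gamma[, , 1], al0$gamma[, , 1], tolerance = 1e-10)
})

test_that("biplot_scores scales loadings by the root singular value", {
  fit <- shared_fit()
  sc <- biplot_scores(fit)
  al <- align_draws(fit)
  d <- 5L; i <- 3L
  expect_equal(sc$gen[d, i, 1],
               sqrt(al$lambda[d, 1]) * al$alpha[d, i, 1], tolerance = 1e-12)
  expect_equal(sc$env[d, 2, 2],
               sqrt(al$lambda[d, 2]) * al$gamma[d, 2, 2], tolerance = 1e-12)
  expect_equal(dim(sc$gen), c(nrow(al$lambda), 20L, 2L))
  expect_equal(rownames(sc$mean_gen), sprintf("G%02d", 1:20))
  expect_error(biplot_scores(fit, axes = c(1, 99)), "exceed")
})

test_that("average_environment returns unit directions", {
  fit <- shared_fit()
  sc <- biplot_scores(fit)
  aea <- average_environment(sc$env)
  ok <- !is.na(aea$dir_draws[, 1])
  expect_equal(rowSums(aea$dir_draws[ok, ]^2), rep(1, sum(ok)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(sum(aea$mean_dir^2), 1, tolerance = 1e-10)
  # the mean point is the mean of environment means: direct recomputation
  expect_equal(aea$point_draws[3, ],
               colMeans(sc$env[3, , ]), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("env_aea_cosine values are cosines and bounded", {
  fit <- shared_fit()
  sc <- biplot_scores(fit)
  cosines <- env_aea_cosine(sc$env)
  expect_equal(nrow(cosines), 7L)
  expect_true(all(cosines$mean >= -1 & cosines$mean <= 1))
  expect_true(all(cosines$lower <= cosines$upper))
  draws <- attr(cosines, "draws")
  expect_true(all(abs(draws) <= 1 + 1e-9, na.rm = TRUE))
  # hand recomputation for one draw and environment
  d <- 2L; j <- 4L
  aea <- average_environment(sc$env)
  s <- sc$env[d, j, ]
  expect_equal(draws[d, j],
               sum(s * aea$dir_draws[d, ]) / sqrt(sum(s^2)),
               tolerance = 1e-12)
})

test_that("ideal_genotype sits on the AEA at the maximal projection", {
  fit <- shared_fit()
  sc <- biplot_scores(fit)
  aea <- average_environment(sc$env)
  ig <- ideal_genotype(sc$gen, aea)
  d <- 7L
  proj <- apply(sc$gen[d, , ], 1, function(s) sum(s * aea$dir_draws[d, ]))
  expect_equal(ig$ideal_draws[d, ], aea$dir_draws[d, ] * max(proj),
               tolerance = 1e-10, ignore_attr = TRUE)
  # distances: hand check for one genotype
  expect_equal(ig$dist_draws[d, 5],
               sqrt(sum((sc$gen[d, 5, ] - ig$ideal_draws[d, ])^2)),
               tolerance = 1e-12)
  expect_true(all(ig$summary$mean >= 0))
  expect_equal(nrow(ig$summary), 20L)
})

test_that("who_won_where matches the inner-product oracle", {
  # hand-made configuration: three clear corner genotypes, one interior
  mean_gen <- rbind(G1 = c(2, 0), G2 = c(-1, 1.5), G3 = c(-1, -1.5),
                    G4 = c(0.1, 0))
  mean_env <- rbind(E1 = c(1, 0.2), E2 = c(-0.5, 1), E3 = c(-0.5, -1))
  www <- who_won_where(mean_gen, mean_env)
  expect_false(www$degenerate)
  expect_false(4 %in% www$hull)             # interior genotype not a vertex
  # oracle: winner maximizes the inner product among hull vertices
  for (j in 1:3) {
    ip <- apply(mean_gen[www$hull, ], 1, function(g) sum(g * mean_env[j, ]))
    expect_equal(unname(www$winner[j]),
                 rownames(mean_gen)[www$hull[which.max(ip)]])
  }
  expect_equal(unname(www$winner), c("G1", "G2", "G3"))
  expect_false(any(www$tied))
})

test_that("who_won_where flags ties and degeneracy", {
  # symmetric configuration: E1 equidistant between G1 and G2
  mean_gen <- rbind(G1 = c(1, 1), G2 = c(1, -1), G3 = c(-2, 0))
  mean_env <- rbind(E1 = c(1, 0))
  www <- who_won_where(mean_gen, mean_env)
  expect_true(www$tied[1])
  expect_equal(unname(www$winner[1]), "G1")  # tie breaks to lower index
  # collinear genotypes
  col_gen <- rbind(G1 = c(0, 0), G2 = c(1, 1), G3 = c(2, 2))
  expect_warning(wd <- who_won_where(col_gen, mean_env), "collinear")
  expect_true(wd$degenerate)
  expect_error(who_won_where(mean_gen[1:2, ], mean_env), "at least 3")
})

test_that("biplot_summary assembles all geometry and plot() runs", {
  fit <- shared_fit()
  bs <- biplot_summary(fit)
  expect_s3_class(bs, "bgge_biplot")
  expect_length(bs$regions_gen, 20L)
  expect_length(bs$regions_env, 7L)
  expect_equal(rownames(bs$cosines), paste0("E", 1:7))
  expect_named(bs$who_won_where$winner, paste0("E", 1:7))
  pdf(NULL)
  on.exit(dev.off())
  out <- plot(fit)
  expect_s3_class(out, "bgge_biplot")
})
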