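#' Align posterior draws across the sign indeterminacy of the SVD
#'
#' Each bilinear axis is only identified up to a joint sign flip of its
#' genotype and environment loadings, and the chain may wander between the
#' two reflections. Per draw, each axis is flipped so that its loadings
#' agree (positive combined inner product) with a fixed reference: the
#' frequentist SVD of the posterior-mean bilinear surface. Genotype and
#' environment sides flip together, so all fitted values are untouched.
#'
#' @param fit a fitted [bgge()] model.
#' @return List of class `"bgge_aligned"` with aligned `alpha`, `gamma`
#'   arrays, the `lambda` draws, reference loadings and the count of
#'   flipped draw-axes.
#' @export
align_draws <- function(fit) {
  mgge <- posterior_mean_gge(fit)
  K <- fit$cfg$k
  sv <- svd_gge(mgge)
  Kr <- min(K, length(sv$lambda))
  Aref <- sv$A[, seq_len(Kr), drop = FALSE]
  Gref <- sv$G[, seq_len(Kr), drop = FALSE]
  alpha <- fit$draws$alpha
  gamma <- fit$draws$gamma
  nd <- dim(alpha)[1]
  flips <- 0L
  for (k in seq_len(Kr)) {
    agree <- alpha[, , k] %*% Aref[, k] + gamma[, , k] %*% Gref[, k]
    neg <- which(agree < 0)
    if (length(neg)) {
      alpha[neg, , k] <- -alpha[neg, , k]
      gamma[neg, , k] <- -gamma[neg, , k]
      flips <- flips + length(neg)
    }
  }
  structure(list(alpha = alpha, gamma = gamma, lambda = fit$draws$lambda,
                 Aref = Aref, Gref = Gref, flips = flips,
                 genotypes = levels(fit$met$records$genotype),
                 environments = levels(fit$met$records$environment)),
            class = "bgge_aligned")
}

#' Posterior biplot score draws
#'
#' Per retained draw, entity scores on the first two bilinear axes with
#' symmetric scaling: axis `a` score of genotype `i` is
#' `sqrt(lambda_a) * alpha_i,a`, and likewise for environments. Draws are
#' sign-aligned first (see [align_draws()]).
#'
#' @param fit a fitted [bgge()] model with `k >= 2`, or a
#'   [align_draws()] result.
#' @param axes which two axes to use (default `c(1, 2)`).
#' @return List with arrays `gen` (`draws x v x 2`) and `env`
#'   (`draws x l x 2`), plus `mean_gen`, `mean_env` matrices and entity
#'   names.
#' @export
biplot_scores <- function(fit, axes = c(1L, 2L)) {
  al <- if (inherits(fit, "bgge_aligned")) fit else align_draws(fit)
  if (max(axes) > ncol(al$lambda))
    stop("requested axes exceed the fitted dimension", call. = FALSE)
  sc <- sqrt(al$lambda[, axes, drop = FALSE])
  gen <- al$alpha[, , axes, drop = FALSE]
  env <- al$gamma[, , axes, drop = FALSE]
  for (j in 1:2) {
    gen[, , j] <- gen[, , j] * sc[, j]
    env[, , j] <- env[, , j] * sc[, j]
  }
  mg <- apply(gen, c(2, 3), mean); rownames(mg) <- al$genotypes
  me <- apply(env, c(2, 3), mean); rownames(me) <- al$environments
  list(gen = gen, env = env, mean_gen = mg, mean_env = me,
       genotypes = al$genotypes, environments = al$environments)
}

#' Highest posterior density interval of a scalar sample
#'
#' Empirical shortest-interval construction: among all contiguous
#' order-statistic windows containing the requested fraction of the sample,
#' the narrowest is returned.
#'
#' @param x numeric sample (length >= 100 recommended).
#' @param level credibility level.
#' @return Numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(x, level = 0.95) {
  xs <- sort(x)
  n <- length(xs)
  m <- max(1L, ceiling(level * n))
  if (m >= n) return(c(xs[1], xs[n]))
  starts <- seq_len(n - m)
  widths <- xs[starts + m] - xs[starts]
  j <- which.min(widths)
  c(xs[j], xs[j + m])
}

# is point p inside (or on) the convex polygon given by hull vertices?
point_in_convex <- function(p, poly) {
  nv <- nrow(poly)
  if (nv < 3L) return(FALSE)
  sgn <- 0
  for (i in seq_len(nv)) {
    a <- poly[i, ]; b <- poly[if (i == nv) 1L else i + 1L, ]
    cr <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    if (abs(cr) < 1e-12) next
    s <- sign(cr)
    if (sgn == 0) sgn <- s else if (s != sgn) return(FALSE)
  }
  TRUE
}

#' Bivariate credible region of a posterior score cloud
#'
#' Points are ranked by Mahalanobis distance from the cloud mean; the
#' innermost `level` fraction is kept and its convex hull is the region
#' boundary. With a numerically degenerate covariance the region falls back
#' to an axis-aligned percentile box (flagged in the result).
#'
#' @param points `n x 2` matrix of aligned score draws.
#' @param level credibility level.
#' @return List of class `"credible_region"`: `boundary` (ordered polygon
#'   vertices), `contains_origin`, `level`, `degenerate`.
#' @export
credible_region <- function(points, level = 0.95) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 100L) stop("need at least 100 draws", call. = FALSE)
  ctr <- colMeans(points)
  S <- stats::cov(points)
  degenerate <- !is.finite(det(S)) || det(S) < 1e-300
  if (!degenerate) {
    Sinv <- tryCatch(solve(S), error = function(e) NULL)
    degenerate <- is.null(Sinv)
  }
  if (degenerate) {
    lo <- apply(points, 2, stats::quantile, (1 - level) / 2)
    hi <- apply(points, 2, stats::quantile, 1 - (1 - level) / 2)
    boundary <- rbind(c(lo[1], lo[2]), c(hi[1], lo[2]),
                      c(hi[1], hi[2]), c(lo[1], hi[2]))
    return(structure(list(boundary = boundary,
                          contains_origin = all(lo <= 0) && all(hi >= 0),
                          level = level, degenerate = TRUE),
                     class = "credible_region"))
  }
  d <- points - matrix(ctr, n, 2, byrow = TRUE)
  md <- rowSums((d %*% Sinv) * d)
  keep <- points[md <= stats::quantile(md, level), , drop = FALSE]
  hull <- keep[grDevices::chull(keep), , drop = FALSE]
  structure(list(boundary = hull,
                 contains_origin = point_in_convex(c(0, 0), hull),
                 level = level, degenerate = FALSE),
            class = "credible_region")
}

#' Average-environment axis (AEA)
#'
#' Per draw, the average of the environment score points defines the
#' average-environment point; the AEA is the unit direction from the biplot
#' origin through it. Draws in which the average vanishes are skipped and
#' counted.
#'
#' @param env_draws `draws x l x 2` array of aligned environment scores.
#' @return List with `dir_draws` (`draws x 2` unit directions, NA rows for
#'   skipped draws), `point_draws` (average-environment points), `mean_dir`
#'   (unit), `mean_point`, `n_skipped`.
#' @export
average_environment <- function(env_draws) {
  if (dim(env_draws)[2] < 1L) stop("need at least one environment",
                                   call. = FALSE)
  pts <- apply(env_draws, c(1, 3), mean)      # draws x 2
  nrm <- sqrt(rowSums(pts^2))
  ok <- nrm > 1e-12
  dirs <- pts / pmax(nrm, 1e-12)
  dirs[!ok, ] <- NA_real_
  mp <- colMeans(pts[ok, , drop = FALSE])
  md <- mp / sqrt(sum(mp^2))
  list(dir_draws = dirs, point_draws = pts, mean_dir = md, mean_point = mp,
       n_skipped = sum(!ok))
}

#' Environment representativeness: cosine with the average-environment axis
#'
#' Per draw, the cosine of the angle between each environment's score
#' vector and the AEA direction; a cosine near 1 marks an environment that
#' ranks genotypes like the average environment does.
#'
#' @param env_draws `draws x l x 2` array of aligned environment scores.
#' @param aea result of [average_environment()] (computed from `env_draws`
#'   if missing).
#' @param level HPD level for the summaries.
#' @return Data frame with per-environment `mean`, `median`, `sd`, `lower`,
#'   `upper`, plus attribute `draws` (the cosine draw matrix).
#' @export
env_aea_cosine <- function(env_draws, aea = NULL, level = 0.95) {
  if (is.null(aea)) aea <- average_environment(env_draws)
  nd <- dim(env_draws)[1]; l <- dim(env_draws)[2]
  cosd <- matrix(NA_real_, nd, l)
  for (j in seq_len(l)) {
    s <- env_draws[, j, ]
    nrm <- sqrt(rowSums(s^2))
    num <- rowSums(s * aea$dir_draws)
    ok <- nrm > 1e-12 & !is.na(num)
    cosd[ok, j] <- num[ok] / nrm[ok]
  }
  rows <- lapply(seq_len(l), function(j) {
    x <- cosd[!is.na(cosd[, j]), j]
    h <- hpd_interval(x, level)
    data.frame(mean = mean(x), median = stats::median(x), sd = stats::sd(x),
               lower = h[1], upper = h[2])
  })
  out <- do.call(rbind, rows)
  attr(out, "draws") <- cosd
  out
}

#' Ideal genotype and distances to it
#'
#' Per draw, the ideal point sits on the average-environment axis at the
#' largest projection of any genotype score onto that axis (the standard
#' GGE-biplot "ideal genotype"); each genotype's merit is its Euclidean
#' distance to that point in the biplot plane.
#'
#' @param gen_draws `draws x v x 2` array of aligned genotype scores.
#' @param aea result of [average_environment()] on the matching environment
#'   draws.
#' @param level HPD level for the distance summaries.
#' @return List with `ideal_draws` (`draws x 2`), `dist_draws`
#'   (`draws x v`), and `summary`, a data frame of per-genotype mean
#'   distance and HPD bounds.
#' @export
ideal_genotype <- function(gen_draws, aea, level = 0.95) {
  nd <- dim(gen_draws)[1]; v <- dim(gen_draws)[2]
  proj <- matrix(NA_real_, nd, v)
  for (i in seq_len(v)) proj[, i] <- rowSums(gen_draws[, i, ] * aea$dir_draws)
  maxproj <- apply(proj, 1, max)
  ideal <- aea$dir_draws * maxproj
  dist <- matrix(NA_real_, nd, v)
  for (i in seq_len(v))
    dist[, i] <- sqrt(rowSums((gen_draws[, i, ] - ideal)^2))
  rows <- lapply(seq_len(v), function(i) {
    x <- dist[!is.na(dist[, i]), i]
    h <- hpd_interval(x, level)
    data.frame(mean = mean(x), lower = h[1], upper = h[2])
  })
  list(ideal_draws = ideal, dist_draws = dist,
       summary = do.call(rbind, rows))
}

#' Who-won-where sectors of the mean-score biplot
#'
#' The convex hull of genotype mean scores forms the polygon;
#' perpendiculars from the origin to its edges split the plane into
#' sectors, and within a sector the hull vertex is the winning genotype of
#' every environment falling there (equivalently, the genotype maximizing
#' the inner product with the environment's score). Ties break to the
#' lower genotype index and are flagged.
#'
#' @param mean_gen `v x 2` matrix of mean genotype scores (rownames used as
#'   labels).
#' @param mean_env `l x 2` matrix of mean environment scores.
#' @return List with `hull` (indices of polygon vertices in input order),
#'   `winner` (per-environment winning genotype label), `tied` (logical
#'   per environment), and `degenerate` flag for collinear score sets.
#' @export
who_won_where <- function(mean_gen, mean_env) {
  v <- nrow(mean_gen)
  if (v < 3L) stop("need at least 3 genotypes", call. = FALSE)
  ctr <- sweep(mean_gen, 2, colMeans(mean_gen))
  degenerate <- abs(det(crossprod(ctr))) < 1e-20
  if (degenerate) warning("genotype scores are (nearly) collinear; ",
                          "sector structure is degenerate")
  hull <- grDevices::chull(mean_gen)
  ip <- mean_env %*% t(mean_gen[hull, , drop = FALSE])   # l x hull
  winner <- character(nrow(mean_env))
  tied <- logical(nrow(mean_env))
  labs <- rownames(mean_gen)
  if (is.null(labs)) labs <- as.character(seq_len(v))
  for (j in seq_len(nrow(mean_env))) {
    best <- max(ip[j, ])
    cand <- which(ip[j, ] >= best - 1e-12)
    idx <- hull[cand]
    winner[j] <- labs[min(idx)]
    tied[j] <- length(cand) > 1L
  }
  names(winner) <- rownames(mean_env)
  list(hull = hull, winner = winner, tied = tied, degenerate = degenerate)
}

#' Full posterior biplot geometry of a fitted model
#'
#' Convenience wrapper assembling mean scores, 95% credible regions for
#' every genotype and environment, the average-environment axis with its
#' point cloud, ideal-genotype distances and who-won-where sectors.
#'
#' @param fit a fitted [bgge()] model with `k >= 2`.
#' @param level credibility level.
#' @return List of class `"bgge_biplot"`.
#' @export
biplot_summary <- function(fit, level = 0.95) {
  sc <- biplot_scores(fit)
  regions_gen <- lapply(seq_along(sc$genotypes), function(i)
    credible_region(sc$gen[, i, ], level))
  names(regions_gen) <- sc$genotypes
  regions_env <- lapply(seq_along(sc$environments), function(j)
    credible_region(sc$env[, j, ], level))
  names(regions_env) <- sc$environments
  aea <- average_environment(sc$env)
  cosines <- env_aea_cosine(sc$env, aea, level)
  rownames(cosines) <- sc$environments
  ideal <- ideal_genotype(sc$gen, aea, level)
  rownames(ideal$summary) <- sc$genotypes
  www <- who_won_where(sc$mean_gen, sc$mean_env)
  structure(list(scores = sc, regions_gen = regions_gen,
                 regions_env = regions_env, aea = aea, cosines = cosines,
                 ideal = ideal, who_won_where = www, level = level),
            class = "bgge_biplot")
}

#' Biplot of a fitted Bayesian GGE model
#'
#' Mean genotype and environment scores on the first two bilinear axes,
#' with credible-region polygons and the average-environment axis.
#'
#' @param x a fitted [bgge()] model.
#' @param regions draw credible-region boundaries.
#' @param level credibility level for the regions.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the [biplot_summary()] used for drawing.
#' @export
plot.bgge <- function(x, regions = TRUE, level = 0.95, ...) {
  bs <- biplot_summary(x, level)
  sc <- bs$scores
  allpts <- rbind(sc$mean_gen, sc$mean_env)
  lim <- range(allpts, 0)
  graphics::plot(NA, xlim = lim, ylim = lim, xlab = "Axis 1",
                 ylab = "Axis 2", asp = 1, ...)
  graphics::abline(h = 0, v = 0, col = "grey80")
  if (regions) {
    for (r in bs$regions_gen)
      graphics::polygon(r$boundary, border = grDevices::adjustcolor("steelblue", 0.5))
    for (r in bs$regions_env)
      graphics::polygon(r$boundary, border = grDevices::adjustcolor("tomato", 0.5))
  }
  graphics::text(sc$mean_gen, labels = sc$genotypes, col = "steelblue4")
  graphics::text(sc$mean_env, labels = sc$environments, col = "tomato3",
                 font = 2)
  graphics::arrows(0, 0, bs$aea$mean_point[1], bs$aea$mean_point[2],
                   length = 0.08, col = "grey40")
  invisible(bs)
}
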