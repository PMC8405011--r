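#' Configuration for the crossover-interaction trial simulator
#'
#' The defaults describe a randomized complete block trial of 20 genotypes in
#' 7 environments with 3 blocks, Gaussian main effects and a sign-structured
#' interaction with three response patterns: genotypes 1-5 interact
#' positively with environments 1-4 and negatively with environments 5-7,
#' genotypes 6-10 show the mirrored crossover, and genotypes 11-20 are
#' stable (unstructured low-variance interaction). All second parameters of
#' the effect distributions are variances.
#'
#' @param v,l,b numbers of genotypes, environments and blocks.
#' @param sigma2_g,sigma2_env,sigma2_blk variances of the genotype,
#'   environment and block main effects.
#' @param sigma2_ge_unstable variance of interaction draws for the two
#'   crossover groups (before sign forcing).
#' @param sigma2_ge_stable variance of interaction draws for the stable group.
#' @param sigma2_eps residual (plot error) variance.
#' @param mu general mean; absorbed by the block effects in any fit, so its
#'   value is inconsequential.
#' @param group1,group2,stable integer indices partitioning `1:v` into the
#'   two crossover groups and the stable group.
#' @param pos_envs,neg_envs integer indices partitioning `1:l` into the
#'   environments where group 1 interacts positively resp. negatively.
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(v = 20L, l = 7L, b = 3L,
                       sigma2_g = 4, sigma2_env = 4, sigma2_blk = 1,
                       sigma2_ge_unstable = 4, sigma2_ge_stable = 1,
                       sigma2_eps = 6, mu = 15,
                       group1 = 1:5, group2 = 6:10, stable = 11:20,
                       pos_envs = 1:4, neg_envs = 5:7) {
  vars <- c(sigma2_g, sigma2_env, sigma2_blk, sigma2_ge_unstable,
            sigma2_ge_stable, sigma2_eps)
  if (any(vars < 0)) stop("variances must be nonnegative", call. = FALSE)
  if (!setequal(c(group1, group2, stable), seq_len(v)) ||
      anyDuplicated(c(group1, group2, stable)))
    stop("group1, group2 and stable must partition 1:v", call. = FALSE)
  if (!setequal(c(pos_envs, neg_envs), seq_len(l)) ||
      anyDuplicated(c(pos_envs, neg_envs)))
    stop("pos_envs and neg_envs must partition 1:l", call. = FALSE)
  structure(list(v = as.integer(v), l = as.integer(l), b = as.integer(b),
                 sigma2_g = sigma2_g, sigma2_env = sigma2_env,
                 sigma2_blk = sigma2_blk,
                 sigma2_ge_unstable = sigma2_ge_unstable,
                 sigma2_ge_stable = sigma2_ge_stable,
                 sigma2_eps = sigma2_eps, mu = mu,
                 group1 = as.integer(group1), group2 = as.integer(group2),
                 stable = as.integer(stable),
                 pos_envs = as.integer(pos_envs),
                 neg_envs = as.integer(neg_envs)),
            class = "sim_config")
}

#' Draw the sign-structured interaction matrix (before centering)
#'
#' Crossover rows are drawn as `|N(0, sigma2_ge_unstable)|` and given the
#' group's sign pattern across environments (absolute-value signing, which
#' preserves the stated marginal scale); stable rows are plain
#' `N(0, sigma2_ge_stable)` draws left untouched.
#'
#' @param cfg a [sim_config()].
#' @return `v x l` numeric matrix. Uses the current RNG stream.
#' @export
draw_interaction <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  m <- matrix(0, cfg$v, cfg$l)
  su <- sqrt(cfg$sigma2_ge_unstable)
  ss <- sqrt(cfg$sigma2_ge_stable)
  sign1 <- ifelse(seq_len(cfg$l) %in% cfg$pos_envs, 1, -1)
  for (i in cfg$group1) m[i, ] <- abs(stats::rnorm(cfg$l, 0, su)) * sign1
  for (i in cfg$group2) m[i, ] <- abs(stats::rnorm(cfg$l, 0, su)) * (-sign1)
  for (i in cfg$stable) m[i, ] <- stats::rnorm(cfg$l, 0, ss)
  m
}

#' Double-center a matrix
#'
#' Removes row and column means (adding back the grand mean), i.e. projects
#' onto the space of pure interaction: all row and column means of the
#' result are zero. Idempotent.
#'
#' @param m numeric matrix.
#' @return Matrix of the same dimension with zero row and column means.
#' @export
double_center <- function(m) {
  sweep(sweep(m, 1L, rowMeans(m)), 2L, colMeans(m)) + mean(m)
}

#' Simulate a multi-environment trial with crossover interaction
#'
#' Responses are built additively:
#' `y = mu + g_i + e_j + blk_{k(j)} + GE_ij + eps`, with Gaussian main
#' effects, the sign-structured interaction of [draw_interaction()]
#' double-centered so that main effects and interaction are orthogonal, and
#' i.i.d. Gaussian plot errors. Block effects are drawn independently within
#' each environment (blocks nested in environments).
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; the output is a deterministic function of
#'   `(cfg, seed)`.
#' @return List with `met` (a [met_table()] of `v*l*b` records) and `truth`,
#'   the generating parameters: `mu`, `g`, `e`, `blk` (`b x l` matrix),
#'   `GE` (double-centered `v x l` matrix) and the residual vector `eps`.
#' @export
simulate_met <- function(cfg = sim_config(), seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  g   <- stats::rnorm(cfg$v, 0, sqrt(cfg$sigma2_g))
  e   <- stats::rnorm(cfg$l, 0, sqrt(cfg$sigma2_env))
  blk <- matrix(stats::rnorm(cfg$b * cfg$l, 0, sqrt(cfg$sigma2_blk)),
                cfg$b, cfg$l)
  GE  <- double_center(draw_interaction(cfg))

  gid <- sprintf("G%02d", seq_len(cfg$v))
  eid <- sprintf("E%d", seq_len(cfg$l))
  bid <- sprintf("B%d", seq_len(cfg$b))
  grid <- expand.grid(gi = seq_len(cfg$v), ei = seq_len(cfg$l),
                      bi = seq_len(cfg$b), KEEP.OUT.ATTRS = FALSE)
  eps <- stats::rnorm(nrow(grid), 0, sqrt(cfg$sigma2_eps))
  y <- cfg$mu + g[grid$gi] + e[grid$ei] + blk[cbind(grid$bi, grid$ei)] +
    GE[cbind(grid$gi, grid$ei)] + eps
  met <- met_table(data.frame(
    genotype = gid[grid$gi], environment = eid[grid$ei],
    block = bid[grid$bi], response = y, stringsAsFactors = FALSE))
  truth <- list(mu = cfg$mu, g = g, e = e, blk = blk, GE = GE, eps = eps,
                cfg = cfg, seed = seed)
  list(met = met, truth = truth)
}
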