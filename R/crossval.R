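#' Random fold assignment for record-level cross-validation
#'
#' Plot records (genotype-environment-block observations) are assigned to
#' folds uniformly at random with fold sizes differing by at most one. The
#' usual removal scenarios are 10-fold (10% held out), 3-fold (33%) and
#' 2-fold (50%), but any number of folds up to `n` is accepted.
#'
#' @param met a [met_table()].
#' @param n_folds number of folds (`>= 2`).
#' @param seed integer seed; the assignment is deterministic given it.
#' @return Integer vector of fold labels, one per record.
#' @export
make_folds <- function(met, n_folds, seed = 1L) {
  stopifnot(inherits(met, "met_table"))
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("need at least 2 folds", call. = FALSE)
  if (n_folds > met$n) stop("more folds than records", call. = FALSE)
  set.seed(seed)
  sample(rep(seq_len(n_folds), length.out = met$n))
}

#' Mean squared prediction error (PRESS)
#'
#' `(1/n) * sum((obs - pred)^2)` over held-out records.
#'
#' @param obs,pred equal-length numeric vectors.
#' @return Scalar PRESS; lower is better.
#' @export
press <- function(obs, pred) {
  if (length(obs) != length(pred)) stop("length mismatch", call. = FALSE)
  mean((obs - pred)^2)
}

#' Predictive correlation
#'
#' Pearson correlation between held-out observations and their predictions.
#'
#' @param obs,pred equal-length numeric vectors, both non-constant.
#' @return Correlation in `[-1, 1]`, or `NA` (with a warning) if either
#'   vector is constant.
#' @export
cor_pred <- function(obs, pred) {
  if (length(obs) != length(pred)) stop("length mismatch", call. = FALSE)
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0) {
    warning("correlation undefined for a constant vector")
    return(NA_real_)
  }
  stats::cor(obs, pred)
}

#' k-fold cross-validation of the Bayesian GGE model
#'
#' For each fold the model is refitted on the remaining records with a full
#' Gibbs run and the held-out records are predicted by the posterior mean of
#' the fitted mean surface ([predict.bgge()]). Held-out records whose
#' genotype or environment vanished entirely from the training set are
#' excluded with a warning.
#'
#' @param met a [met_table()].
#' @param n_folds number of folds.
#' @param variant prior variant passed to [bgge()].
#' @param k bilinear dimension of the refits; default the maximal rank of
#'   the full data.
#' @param plan [mcmc_plan()] for the refits (typically shorter than the
#'   headline fit).
#' @param seed integer seed controlling both the fold assignment and the
#'   refits.
#' @return Object of class `"bgge_cv"`: data frame of per-fold `PRESS` and
#'   `COR` plus attributes `mean_press`, `mean_cor`, `sd_press`, `sd_cor`.
#' @export
run_cv <- function(met, n_folds, variant = c("entropy", "flat"), k = NULL,
                   plan = mcmc_plan(n_keep = 1000L, thin = 2L,
                                    burn_in = 1000L),
                   seed = 1L) {
  variant <- match.arg(variant)
  if (is.null(k)) k <- met$t
  folds <- make_folds(met, n_folds, seed)
  rec <- met$records
  rows <- lapply(seq_len(n_folds), function(f) {
    train <- rec[folds != f, , drop = FALSE]
    test <- rec[folds == f, , drop = FALSE]
    train$genotype <- droplevels(train$genotype)
    train$environment <- droplevels(train$environment)
    train$block <- droplevels(train$block)
    tmet <- met_table(train)
    fit <- bgge(tmet, k = min(k, tmet$t), variant = variant, plan = plan,
                seed = seed + f)
    pred <- predict(fit, newdata = test)
    ok <- !is.na(pred)
    data.frame(fold = f, n_test = sum(ok),
               PRESS = press(test$response[ok], pred[ok]),
               COR = cor_pred(test$response[ok], pred[ok]))
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_press") <- mean(out$PRESS)
  attr(out, "mean_cor") <- mean(out$COR)
  attr(out, "sd_press") <- stats::sd(out$PRESS)
  attr(out, "sd_cor") <- stats::sd(out$COR)
  attr(out, "variant") <- variant
  class(out) <- c("bgge_cv", "data.frame")
  out
}

#' @export
print.bgge_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s prior)\n", nrow(x),
              attr(x, "variant")))
  print.data.frame(x)
  cat(sprintf("mean COR = %.3f (sd %.3f), mean PRESS = %.3f (sd %.3f)\n",
              attr(x, "mean_cor"), attr(x, "sd_cor"),
              attr(x, "mean_press"), attr(x, "sd_press")))
  invisible(x)
}
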