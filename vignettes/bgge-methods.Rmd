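---
title: "Bayesian GGE models with maximum-entropy shrinkage: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian GGE models with maximum-entropy shrinkage: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgge)
```

## The model

Multi-environment trials evaluate `v` genotypes in `l` environments
(locations), laid out in `b` complete blocks within each environment. The
GGE (site regression) model analyses the genotype main effect and the
genotype-by-environment interaction *jointly*, which is what matters for
cultivar recommendation: a genotype is useful because of its total
performance in an environment, not because of how that performance splits
into main effect and interaction. The observation model is linear-bilinear:

$$
y_{ijr} = \beta_{jr} + \sum_{k=1}^{K} \lambda_k \alpha_{ik} \gamma_{jk}
          + \varepsilon_{ijr},
\qquad \varepsilon_{ijr} \sim N(0, \sigma^2_e),
$$

where $\beta_{jr}$ is the fixed effect of block $r$ within environment $j$
(absorbing the general mean and the environment main effect), and the
bilinear term is a rank-$K$ singular value decomposition of the G+GE
surface: singular values $\lambda_1 \ge \dots \ge \lambda_K \ge 0$,
orthonormal genotype loadings $\alpha_k$ and environment loadings
$\gamma_k$. The maximal rank is $t = \min(v - 1, l)$. In matrix form, the
frequentist analogue environment-centers the cell-mean matrix (column
centering only — genotype information stays inside) and takes its SVD;
`center_gge_matrix()` and `svd_gge()` implement that reference
decomposition.

## Two priors on the singular values

Both variants use a huge-variance normal prior on $\beta$ and Jeffreys'
prior on $\sigma^2_e$. They differ only in the prior on each singular
value, which is (half-)normal with variance $\sigma^2_{\lambda_k}$:

* **Flat variant** (`variant = "flat"`): $\sigma^2_{\lambda_k} = 10^8$,
  fixed. The posterior essentially reproduces the likelihood solution;
  every sampled axis keeps a nonzero singular value, and the analyst must
  choose the dimension afterwards with information criteria.

* **Entropy variant** (`variant = "entropy"`): each
  $\sigma^2_{\lambda_k}$ gets a maximum-entropy hierarchical prior. Among
  all priors on a variance with given constraints, the maximum-entropy
  choice adds the least extra information; working it out for this model
  yields an inverse-gamma full conditional

  $$
  \sigma^2_{\lambda_k} \mid \cdot \;\sim\;
  \mathrm{GI}\!\left(a + 1,\; \lambda_k^2 + 2b\right),
  \quad a = 1,\; b = 0,
  $$

  in the convention where $\mathrm{GI}(s, c)$ has density proportional to
  $x^{-(s+1)} e^{-c/(2x)}$, i.e. the draw is $c / \chi^2_{2s}$ and the
  conditional mean is $\lambda_k^2 / 2$. A weakly supported axis therefore
  gets a small variance, which pins its singular value near zero at the
  next update — and a singular value near zero keeps the variance small.
  This feedback loop makes noise axes collapse (posterior means around
  $10^{-6}$) while well-supported axes survive almost unshrunk, so the
  model performs continuous, automatic dimension selection inside the
  sampler.

In practice the collapse is sharp: on the study's simulated trials, axes
whose frequentist singular value is below roughly 12 collapse outright,
while axes above roughly 16 survive with mild attenuation. The result is a
posterior that concentrates on the two structured interaction axes of the
generator and discards the rest.

## Full conditionals and the Gibbs sampler

All full conditionals are standard forms, sampled in a systematic scan
(`gibbs_run()`):

* $\beta \mid \cdot$ — normal. The incidence structure makes the
  precision diagonal, so the update is elementwise:
  mean $(X_1'X_1 + (\sigma^2_e/\sigma^2_\beta) I)^{-1} X_1'(y - M)$ with
  the current bilinear fit $M$, and matching covariance.
* $\lambda_k \mid \cdot$ — normal, truncated to
  $[\lambda_{k+1}, \lambda_{k-1}]$ so the order constraint holds draw by
  draw (`rtruncnorm1()` uses log-space inverse-CDF sampling, stable in
  extreme tails).
* $\sigma^2_{\lambda_k} \mid \cdot$ — the inverse-gamma above (entropy
  variant only), with a tiny floor so a collapsed axis leaves the next
  conditional proper.
* $\alpha_k, \gamma_k \mid \cdot$ — von Mises-Fisher. Orthogonality to
  the other same-side loadings is enforced by sampling in the corrected
  subspace: with $H$ an orthonormal basis of the complement and
  $h = H' L_k'(y - X_1\beta)$, the auxiliary vector is vMF with mean
  direction $h/\lVert h\rVert$ and concentration
  $\lVert h\rVert \lambda_k / \sigma^2_e$, mapped back through $H$.
  `rvmf()` implements Wood's rejection sampler, with a two-point special
  case in dimension one and an exact large-concentration limit
  ($\kappa(1 - w) \sim \mathrm{Gamma}((m-1)/2, 1)$) where the envelope
  loses floating-point precision.
* $\sigma^2_e \mid \cdot$ — scaled inverse chi-square with $n$ degrees of
  freedom and scale $\mathrm{SSE}/n$.

### Missing records and data augmentation

The vMF conditionals are exact only on a complete balanced
genotype-by-environment-by-block grid: with records missing, the residual
quadratic form $\lambda_k^2 \sum_{ij} n_{ij}\alpha_{ik}^2\gamma_{jk}^2$
depends on the loading being sampled and the conditional stops being vMF.
The sampler therefore treats unobserved plots of the grid as latent
variables and imputes them from the current fitted mean and residual
variance at the top of every scan (data augmentation, as in the Bayesian
AMMI literature this model descends from). That keeps every conditional
exact at the cost of one extra Gaussian draw per missing plot. Reported
log-likelihoods always use observed records only.

This matters in practice: without augmentation the chain is biased
whenever cells are unbalanced — on noise-free data with held-out records
it visibly drifts away from an exactly-fitting state. With augmentation,
held-out noise-free records are recovered exactly (predictive correlation
1, PRESS at numerical zero).

### Identifiability and alignment

Each bilinear axis is identified only up to a joint sign flip of
$(\alpha_k, \gamma_k)$. The sampler does not constrain the sign, so before
averaging loadings across draws, `align_draws()` flips each draw-axis to
agree with a fixed reference (the SVD of the posterior-mean bilinear
surface, which is itself sign-invariant). Fitted values are untouched by
alignment.

## Chain planning and diagnostics

The run-length rule is $N = n_{\text{keep}} \cdot J + B$: a pilot chain is
diagnosed with Raftery-Lewis (`raftery_lewis()`), the thinning $J$ is the
largest dependence factor (rounded up), and the burn-in $B$ is the largest
suggested burn-in floored at 10,000 (`plan_run()`). Convergence reports
(`diagnose()`) monitor every singular value, the residual variance and the
entropy-variant singular-value variances with:

* Raftery-Lewis run lengths (dichotomize at the 2.5% quantile, choose the
  thinning by a BIC comparison of first- versus second-order two-state
  Markov chains, read burn-in and required length off the fitted
  transition matrix);
* Heidelberger-Welch stationarity (Cramér-von Mises statistic against the
  spectral density at zero estimated from the second half by an AR fit,
  iteratively discarding 10% heads) and the relative halfwidth test;
* effective sample size (Geyer's initial monotone sequence estimator,
  capped at the chain length).

One honest caveat, verified empirically: with the iterative discard scheme
and an AR-based spectral estimate, the stationarity flag cannot turn
`FALSE` when the chain's second half is internally consistent, because the
last window tested is the very segment the variance was estimated from.
The diagnostic's real contract is that contaminated windows are rejected
and discarded; treat the retained fraction, not the flag alone, as the
signal.

## Model selection

For the flat variant the dimension must be chosen explicitly; the package
tabulates (`selection_table()`):

* plug-in AIC and BIC at posterior means with
  $\mathrm{df} = bl + k(v + l - k) + 1$;
* AICM $= 2\,\mathrm{var}(\ell) - 2\,\mathrm{mean}(\ell)$ from the
  posterior log-likelihood draws (no plug-in needed);
* the kernel-density posterior mode of $\sigma^2_e$ per dimension
  (`sigma_profile()`) — once it flattens, further axes refit noise;
* the information rate
  $\mathrm{IR}_k = \lambda_k^2 / (\sum_k \lambda_k^2 / t)$
  (`information_rate()`): axes with $\mathrm{IR}_k > 1$ carry more than
  one variable's worth of structure; the first $\mathrm{IR}_k < 1$ axis
  and all later ones read as noise.

Under the entropy variant these criteria mostly confirm what the shrinkage
already did.

## Cross-validation

`run_cv()` implements random k-fold removal of plot records (10%, 33%,
50% for 10-, 3-, 2-fold), refits per fold — the removed records are
latent, so the refit uses exactly the augmented sampler above — and
scores held-out records by the Rao-Blackwellized posterior-mean surface.
Reported are per-fold PRESS (mean squared prediction error) and COR
(Pearson correlation of observation and prediction), with means and
standard deviations across folds.

## Posterior biplot inference

All biplot geometry is computed per draw and summarized, so every
statement carries posterior uncertainty (`biplot_summary()`):

* scores with symmetric scaling $\sqrt{\lambda_a} \cdot$ loading;
* 95% bivariate credible regions: innermost 95% of each entity's score
  cloud by Mahalanobis rank, convex-hulled;
* the average-environment axis (AEA): unit direction through the per-draw
  mean environment point;
* environment representativeness: per-draw cosine between each
  environment's score and the AEA, with HPD intervals (`hpd_interval()`
  uses the shortest order-statistic window);
* the ideal genotype: the point on the AEA at the largest genotype
  projection, with per-genotype Euclidean distance summaries;
* who-won-where: convex hull of mean genotype scores; each environment's
  winner maximizes the inner product among hull vertices (ties flagged,
  broken to the lower index).

`plot()` on a fitted model draws the mean-score biplot with credible
regions and the AEA. Mega-environment follow-up uses `subset_mega()` to
re-analyse homogeneous environment subsets.

## The trial simulator

`simulate_met()` generates the crossover-interaction design used
throughout the package's reference analyses: 20 genotypes, 7 environments,
3 blocks; genotype and environment effects $N(0, 4)$, block effects
$N(0, 1)$, residuals $N(0, 6)$; an interaction with two crossover groups
(genotypes 1-5 positive in environments 1-4 and negative in 5-7,
genotypes 6-10 mirrored, magnitudes $|N(0, 4)|$) and ten stable genotypes
($N(0, 1)$), double-centered so the interaction is orthogonal to the main
effects. Fitting the entropy variant at full rank to such data collapses
all but the first two axes — the two crossover groups are exactly the
structure the shrinkage keeps.

A caveat for anyone comparing against published tables of this design:
the first two moments one obtains under this variance reading do not
reproduce every published number simultaneously (the published full-rank
spectrum implies a larger genotypic scale than the published residual
variance and predictive correlations do). The package keeps the stated
distributional design; where a larger-scale spectrum is needed, pass
explicit variances (e.g. `sigma2_g = 16`) rather than reinterpreting the
defaults.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_met(sim_config(), seed = 1)
fit <- bgge(sim$met, variant = "entropy", seed = 1)   # k defaults to t = 7
summary(fit)
diagnose(fit)
plot(fit)                                             # posterior biplot

# flat variant over a dimension grid, with selection criteria
fits <- lapply(1:7, function(k) bgge(sim$met, k = k, variant = "flat",
                                     seed = 1))
selection_table(fits)

# predictive assessment
run_cv(sim$met, 10, variant = "entropy", seed = 1)
```

Default chains (`mcmc_plan()`: 4,000 retained draws, thinning 20, burn-in
10,000) take a few minutes per full-rank fit at the study's size
(420 records); the shorter plans used in the examples and tests finish in
seconds and already show the qualitative behavior.
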