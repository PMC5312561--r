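---
title: "Comparing one-stage and two-stage IPD meta-analysis of binary outcomes by simulation"
author: "ipdmasim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing one-stage and two-stage IPD meta-analysis of binary outcomes by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipdmasim)
```

## The question the package addresses

When individual patient data (IPD) from several randomized studies of a
binary outcome are pooled, the analyst chooses between a *two-stage*
approach — fit a logistic regression per study, then meta-analyze the
per-study log odds ratios — and a *one-stage* approach — fit a single
logistic generalized linear mixed model (GLMM) to all subjects with
study-level random effects. Within the one-stage family there are further
choices: the estimation procedure (penalized quasi-likelihood, PQL, versus
adaptive Gauss–Hermite quadrature, AGHQ) and whether the study baseline
risks are modelled as random draws or as separate fixed ("stratified")
intercepts. `ipdmasim` provides the data generators, the four estimators
and the Monte-Carlo machinery needed to compare these choices in terms of
bias, root mean squared error, Wald coverage and numerical convergence of
the pooled treatment effect $\beta_1$ (a log odds ratio) and of the
between-study variance of the treatment effect $\tau_1^2$.

## Data-generating models

Each dataset has two levels: subjects $i = 1, \dots, n_j$ within studies
$j = 1, \dots, K$. The exposure $x_{ij}$ is a fair Bernoulli draw recoded
to $\pm 1/2$, and the outcome is Bernoulli with

$$\mathrm{logit}(\pi_{ij}) = (\beta_0 + b_{0j}) + (\beta_1 + b_{1j}) x_{ij}$$

in *random-intercept* mode, with $(b_{0j}, b_{1j})$ bivariate normal with
variances $(\tau_0^2, \tau_1^2)$ and correlation $\rho$; or

$$\mathrm{logit}(\pi_{ij}) = \beta_j + (\beta_1 + b_{1j}) x_{ij}$$

in *stratified-intercept* mode, where each $\beta_j$ is an independent
uniform draw and $b_{1j} \sim N(0, \tau_1^2)$.

The generator's defaults are the study conditions of the comparison:
$\beta_0 = -0.85$ (a 30% outcome prevalence at the null, since
$\mathrm{expit}(-0.85) = 0.299$), $\beta_1 = 0.18$, variances
$\tau_0^2, \tau_1^2 \in \{0.05, 1, 4\}$ — corresponding to heterogeneity
fractions $I^2 = \tau^2/(\tau^2 + \pi^2/3) \approx 0.01, 0.23, 0.55$ on
the log-odds scale — correlations $\rho \in \{0, 0.5\}$, and six
size designs: $K = 5$ or $15$ studies with average total sample sizes
$N = 500$ or $3000$, balanced or imbalanced. Imbalanced designs make 25%
of studies (rounded) ten times larger than the rest, which reproduces
large-study sizes of 357 ($K=5$, $N=500$), 98 ($K=15$, $N=500$) and 588
($K=15$, $N=3000$). Sensitivity settings (5% prevalence via
$\beta_0 = \mathrm{logit}(0.05) \approx -2.944$; $K = 50$, $N = 9000$)
are ordinary configuration values, not special cases.

Two choices in the generator were genuinely open and are fixed as
follows:

* **Uniform range of the stratified intercepts.** Only the family
  (uniform) of the stratified draws is part of the design, not its range.
  We center the uniform at $\beta_0$ with half-width $\tau_0\sqrt{3}$, so
  its mean is $\beta_0$ and its variance is exactly $\tau_0^2$. This makes
  the two generation modes variance-matched and their comparison
  meaningful.
* **Imbalanced allocation.** With $K_L = \mathrm{round}(0.25K)$ large
  studies, the small-study size is $s = N/(K - K_L + 10 K_L)$, rounded to
  the nearest integer, and large studies get $\mathrm{round}(10s)$. This
  is the unique reading that reproduces all three printed large-study
  sizes above.

The full crossing of the listed factors yields 216 scenarios
(`default_scenario_grid()`). The generator emulates randomized two-arm
trials with a single binary exposure and no covariates; real IPD-MA
features such as covariate imbalance, non-randomized designs, missing
data, more than two arms, or non-normal random slopes are outside its
scope, so passing tests say nothing about robustness to those features.

## The four estimators

**Two-stage, first stage.** Each study is fit by maximum-likelihood
logistic regression of outcome on exposure (IRLS). Because the model is
saturated for a binary exposure, the fit equals the closed-form 2×2-table
estimate: the log odds ratio with variance $1/a + 1/b + 1/c + 1/d$ and,
with the $\pm 1/2$ coding, an intercept equal to the mean of the two arm
logits. Small studies (10 subjects at 30% prevalence) frequently produce
zero cells; we then add 0.5 to all four cells (Haldane–Anscombe) and flag
the study, so the first stage always returns finite estimates. Studies
whose subjects all fell into one arm carry no information about the odds
ratio and are dropped from the second stage with their ids recorded.

**Model 1 — bivariate REML** (`pool_bivariate_reml()`). The per-study
intercept and slope estimates are synthesized jointly under
$(\hat\gamma_{0j}, \hat\gamma_{1j})^\top \sim N((\gamma_0, \gamma_1)^\top,
\Sigma + C_j)$ with known within-study covariance $C_j$. The between-study
covariance $\Sigma$ is parameterized by its Cholesky factor and estimated
by restricted maximum likelihood with a quasi-Newton optimizer from two
starts (a small diagonal, and a method-of-moments start); the pooled
effect and its SE come from generalized least squares at $\hat\Sigma$, and
the SE of $\hat\tau_1^2$ from the numerically differentiated REML Hessian
on the variance scale.

**Model 2 — DerSimonian–Laird** (`pool_dl()`). The classical
non-iterative method-of-moments estimator: Cochran's $Q$ with
inverse-variance weights, $\hat\tau_1^2$ truncated at zero, and
random-effects inverse-variance pooling. It reports no SE or interval for
$\hat\tau_1^2$.

**Model 3 — random intercept + random slope GLMM** and **Model 4 —
stratified intercepts + random slope GLMM**, each fit by two engines
(`fit_pql()`, `fit_aghq()`). Both operate on the per-study-per-arm
binomial counts, which are sufficient for these models.

* *PQL* iterates the Breslow–Clayton linearization: working response
  $z = \eta + (y - \mu)/(\mu(1-\mu))$ and weights $n\mu(1-\mu)$, a
  working linear mixed model fit by REML (the Breslow–Clayton
  default) over the Cholesky-parameterized random-effects
  covariance, and BLUP updates of the linear predictor, until every fixed
  effect and variance component changes by less than $10^{-8}$ or 100
  iterations are reached.
* *AGHQ* maximizes the marginal likelihood, whose per-study integrals
  (two-dimensional for Model 3, one-dimensional for Model 4) are
  approximated by Gauss–Hermite quadrature recentered and rescaled at
  each study's conditional mode. The number of points per dimension
  starts at 5 and doubles (5, 10, 20, 40) until the maximized
  log-likelihood changes by less than $10^{-4}$; this documented doubling rule replaces the
  undisclosed automatic selection rules of commercial mixed-model
  software.
  One point reproduces the Laplace approximation exactly. For Model 4 the
  $K$ stratified intercepts are profiled out with an inner per-study
  Newton search, keeping the outer quasi-Newton problem two-dimensional
  regardless of $K$.

**Convergence bookkeeping.** A fit is recorded as non-converged when the
iteration cap is hit, an inner solver fails, the likelihood Hessian is
not positive definite, or the estimated random-effects covariance is at
a boundary (smallest eigenvalue below $10^{-8}$, which captures zero
variances and $|\rho| \to 1$). Non-converged fits still contribute their
finite estimates to bias and MSE — discarding them would condition the
performance summaries on convergence and bias the comparison; non-finite
estimates are excluded with a logged count.

## Assessment criteria

For each scenario × method cell, `summarize_fits()` reports the
convergence percentage, and for $\beta_1$ and $\tau_1^2$: the
Monte-Carlo mean bias, its absolute value, MSE, RMSE, the Wald coverage
percentage (covered iff $|\hat\theta - \theta| \le 1.96\,
\mathrm{SE}(\hat\theta)$, boundary inclusive), and the median and
quartiles of the per-replicate absolute error. Two aggregations of
"absolute bias" are emitted deliberately: the absolute mean bias per
cell, and the per-replicate absolute-error distribution, because the
published "median (25th, 75th percentile)" cell format cannot be
attributed unambiguously to a single population of values; reporting both
lets either reading be compared. Coverage of $\tau_1^2$ uses the same
1.96 rule on the untransformed variance scale; no log transform or
$t$-correction is applied.

## Reproducibility design

Seeds form a hierarchy: a master seed, a canonical per-scenario key
derived from the scenario's content (not its position in the grid), and
the replicate index, mixed by modular multiplicative steps below
$2^{31}$. Consequences: any single replicate can be regenerated in
isolation; all methods within a replicate see the identical dataset
(paired comparison); results are bit-identical regardless of scenario
order or parallel scheduling; and extending the number of replicates
preserves the prefix of the stream. `run_experiment()` checkpoints each
completed scenario as tab-separated text and resumes interrupted runs
from those files.

## Numerical choices

* Variance matrices are always parameterized through Cholesky factors, so
  positive semidefiniteness is structural, with boundary estimates
  detected by an eigenvalue threshold of $10^{-8}$ rather than by
  optimizer failure.
* The bivariate REML objective ridges a study's marginal covariance by
  $10^{-10}$ if it is numerically singular, and records a message;
  persistent singularity is non-convergence.
* The AGHQ mode search is a damped Newton iteration converged to a
  gradient below $10^{-11}$; integrand sums use log-sum-exp.
* IRLS in the first stage converges at a relative coefficient change of
  $10^{-10}$ (cap 50); the closed form, which always exists after the
  continuity correction, is the fallback.
* Working-response probabilities are clipped to $[10^{-10},
  1 - 10^{-10}]$ to keep PQL weights finite.

## Problem sizes used in the packaged checks

The full 216-scenario × 1000-replicate grid is a cluster-scale
computation. The packaged test suite and the acceptance script instead
re-run selected cells at sizes a desktop handles in minutes, chosen
before looking at any outcome: the two-stage estimator at 1000
replicates (small- and large-sample imbalanced scenarios with
$\tau_0^2 = \tau_1^2 = 1$, $\rho = 0.5$), the one-stage PQL model at 300
replicates, and both one-stage engines at 200 replicates for parameter
recovery. Analytic identities (the $I^2$ mapping, the 30% prevalence) are
exact. All estimator-level properties are checked against independent
oracles: closed-form 2×2 arithmetic, a hand DerSimonian–Laird
calculation, a univariate-REML grid search, dense 201×201 trapezoid
integration of the marginal likelihood, a brute-force nested
penalized-likelihood optimization, and cross-checks against `metafor`,
`MASS::glmmPQL` and `lme4::glmer`, which implement the same standard
methods independently.

## Known limitations

* PQL's small-cluster bias for binary outcomes is a property of the
  method, not removed here; the framework quantifies it.
* The stratified one-stage model estimates $K$ intercepts from few
  events per study and is boundary-heavy at high heterogeneity; those
  fits are flagged via the non-convergence rule rather than hidden.
* Wald intervals for $\tau_1^2$ on the variance scale under-cover
  severely; that under-coverage is part of what the framework measures,
  and no alternative interval (profile, Q-profile) is provided.
* The quadrature-point selection rule and the first-stage separation
  handling are deliberate, documented choices (doubling rule;
  Haldane–Anscombe correction) and are flagged per study where they
  act; other defensible choices exist for both.
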