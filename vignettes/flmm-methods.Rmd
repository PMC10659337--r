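---
title: "Functional mixed models for trial-level signals: model, inference and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional mixed models for trial-level signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(flmm)
```

## The model

A trial-structured functional dataset is a matrix `Y` with one row per
trial and one column per time-point of a common, equally spaced grid
(seconds relative to an alignment event such as cue onset or the first
lick after reward delivery), bound to a trial table carrying subject,
session and trial identifiers plus scalar covariates. At every grid
column `s` the package fits the Gaussian linear mixed model

$$ E[\,Y_i(s) \mid X_i, Z_i, \gamma_i(s)\,] = X_i \beta(s) + Z_i \gamma_i(s), $$

so each fixed-effect coefficient becomes a function $\beta_k(s)$ over
trial time and each random effect becomes a subject- (or session-)
specific deviation function $\gamma_i(s)$. Models are written in lme4
syntax restricted to a deliberate sublanguage: `+`-separated fixed terms
with `:` interactions, and random blocks `(terms | g)`, `(terms | a/b)`
(nested, expanded to `a` and `a:b`) or `(terms | a:b)`. The per-column
fits are ordinary scalar mixed models and are delegated to `lme4::lmer`
(REML by default, deterministic restarts at rescaled variance components
on non-convergence); boundary fits are accepted. Columns with missing
samples drop only the affected rows at that column. AIC/BIC are the ML
criterion evaluated at the fitted components, summed over converged
columns, with the column set recorded so that models are only compared
on identical sets.

## Smoothing

Raw coefficient curves $\tilde\beta_k(s)$ are smoothed with cubic
B-splines: `K = min(ceiling(S/2), 30)` basis functions on equally spaced
knots with a second-order difference penalty available. The smoother is
an explicit linear operator $H_k$, so constants and straight lines pass
through exactly and variance propagation through the smoother is exact
rather than approximate. By default the penalty weight is zero — the
smoothing comes from the basis dimension alone. This was a genuinely
open design choice, resolved by measurement: per-coefficient GCV
selection (available via `smoother_spec(lambda = "auto")`, log-spaced
grid $10^{-4}\dots10^{8}$, near-ties resolved to the smoother fit) makes
the selected smoother a function of the realized noise, and the band
variance — which must treat the smoother as fixed — then understates the
estimator's variability. At the packaged template conditions this
selection optimism raises the null joint rejection rate from 0.055 to
0.080. A noise-independent smoother restores validity; GCV remains the
right tool for exploratory point estimation. BLUP curves are smoothed
with the same specification for reporting.

## Covariance of the smoothed estimator

The methodological core is the cross-time-point covariance of the raw
GLS estimators, which supports nested random effects. Writing
$M(s) = (X'V^{-1}X)^{-1}X'V^{-1}$ for the per-column GLS weights at the
fitted components,

$$ \mathrm{Cov}(\tilde\beta(s_1), \tilde\beta(s_2)) =
   \sum_k M(s_1) Z_k \hat G_k(s_1,s_2) Z_k' M(s_2)' +
   \hat\sigma_\varepsilon(s_1,s_2)\, M(s_1) M(s_2)' . $$

The cross-covariances $\hat G_k(s_1,s_2)$ (one matrix per random group,
including nested levels) and $\hat\sigma_\varepsilon(s_1,s_2)$ are
method-of-moments estimates: with marginal residuals
$e(s) = y(s) - X\hat\beta(s)$ and the OLS hat matrix $H_X$ as a proxy for
the per-column GLS hat, $E[e(s_1)e(s_2)'] = (I-H_X)V(s_1,s_2)(I-H_X)'$
exactly, which stays linear in the unknown coordinates. Least squares
over all index pairs — computed in factored form without building any
$L \times L$ matrix — therefore gives unbiased estimates with no
shrinkage and no ad hoc degrees-of-freedom factor. (A plug-in
alternative using BLUP cross-products was evaluated and rejected: BLUP
shrinkage attenuates cross-covariances severely at small subject counts,
which destroys band coverage.)

Three denoising steps follow, each preserving unbiasedness to first
order:

* every moment surface is smoothed along its lag-diagonals (each lag
  curve is smooth under the model, while the ridge across lags — short-
  range error correlation plus any white nugget — is left intact);
* the same-time-point diagonal uses the per-column model-based variance,
  denoised by smoothing log-variance along the grid;
* the assembled surface is pre/post-multiplied by the coefficient's
  smoother matrix, symmetrized, and projected to the nearest positive
  semi-definite matrix by eigenvalue truncation at zero, whose diagonal
  defines the squared pointwise standard errors.

## Pointwise and joint bands

Pointwise intervals are Gaussian, $\hat\beta_k(s) \pm z_{0.975}\,se(s)$.
The joint (simultaneous) band replaces $z$ with the empirical `level`
quantile of $\max_s |Z_s|/\sqrt{C_{ss}}$ over 10,000 Monte-Carlo draws
$Z \sim N(0, C)$ (fixed, recorded seed), never below the pointwise
critical value, with a separate band per coefficient. Because the
variance estimate itself is noisy when few subjects carry the dominant
variance component, the multiplier draws are additionally studentized by
a common $\chi^2_\nu/\nu$ scale. The degrees of freedom $\nu$ are the
Satterthwaite df of the *integrated* variance, estimated by a
delete-one-subject jackknife of the moment step (smoother and sandwich
weights held fixed): per-point jackknife noise cancels in the integral,
leaving exactly the shared scale noise that the common-scale model
represents. This adjustment has no tunable constant; it leaves the
pointwise intervals untouched (their coverage is already nominal) and
widens only the maximum statistic, which is what variance noise
actually distorts. Periods where the joint band excludes zero are
significant simultaneously over the whole trial. A cluster bootstrap
over subjects (percentile pointwise bands, max-deviation joint
multiplier, minimum 200 replicates) is provided for outcomes where the
Gaussian analytic bands are suspect.

## The synthetic-data generator

`sim_truth()`/`generate_functional()` implement the generative model

$$ Y_{ijl}(s) = \beta_0(s) + \gamma_{0,i}(s) +
   \mathrm{delay}_{il}\,(\beta_1(s) + \gamma_{1,i}(s)) \;[+\,\gamma_{0,il}(s)]\; +
   \varepsilon_{ijl}(s), $$

with subject curves drawn once per subject from $N(0, \Sigma^\gamma_k)$,
an optional session-level nested intercept curve, and error curves drawn
independently per trial from $N(0,\, 5 \cdot \Sigma^\varepsilon_{m(i)})$
— the factor 5 is the design's stated error inflation. The base-matrix
index follows the stated assignment rule: for $n \le M$ (default
$M = 7$) indices are drawn uniformly without replacement; for $n > M$
the first $M$ subjects take indices $1..M$ and the remainder are drawn
without replacement, inducing the intended cross-subject error coupling.
Defaults: 15 Hz sampling, 100 trials per session, condition switching
between sessions, inter-reward intervals exponential with mean 14 s.

The reference covariance matrices of the source experiments are
estimated from real data and are not published, so the generator
substitutes parametric stand-ins (squared-exponential or AR(1) families;
user-supplied matrices are accepted for exact replication). The
calibration of the packaged `delay_template()` reflects two constraints
taken from the design itself rather than from convenience: (i) the
error-dominated variance regime — the design multiplies the residual
covariance by 5 precisely so that within-trial error curves dominate,
and single-trial photometry traces are far noisier than the mean
transient — realized here as base error variances 0.15–0.33 (trial
noise sd ≈ 0.9–1.3 after scaling) against a transient of amplitude 2
and slope-heterogeneity sd 0.15; and (ii) error-curve lengthscales of
0.1–0.4 s with a 5% white nugget, consistent with indicator kinetics of
100–500 ms. The condition effect is biphasic (positive lobe at 0.35 s,
negative lobe of 25% amplitude at 1.3 s), exercising the bands on
sign-changing effects; its amplitude (0.75) is set so that the windowed
AUC t-test at n = 7 has power strictly between 0.2 and 0.9, keeping the
method comparison informative. What the generator does *not* emulate:
photobleaching trends, isosbestic channels, raw photon counts,
behaviorally-gated trial exclusions. Passing coverage here demonstrates
calibration under the stated generative model, not under arbitrary real
-data violations of it.

Two delay pairings (3/9 s and 2/8 s) are quoted for the source
delay-change experiment in different places; `event_config()` defaults
to 3/9 and accepts either.

## Simulation experiments and problem sizes

`run_coverage_experiment()` and `run_power_experiment()` regenerate,
refit and score replicates under a fixed master seed (per-replicate
seeds drawn once from it). Reported rates carry binomial Monte-Carlo
standard errors, and replicate counts below 100 set a small-sample flag.
The packaged problem sizes are 7 subjects, 2 sessions and a 45-point
15 Hz grid with 20 trials per session per replicate — the trial count is
the deliberate desk-scale reduction from the 100-trial default, chosen
so a full 500-replicate experiment completes in minutes. At these sizes
the measured operating characteristics (250–500 replicates) are: joint
coverage ≈ 0.95–0.96, pointwise coverage ≈ 0.95, null joint rejection
≈ 0.05–0.06, and a power ordering of joint bands ≈ 0.95 versus windowed
t-test ≈ 0.2–0.3.

## Numerical choices and limitations

* Grid validation requires equal spacing (1e-8 relative); signal columns
  are zero-based `sig0..sig{S-1}` in the wide CSV dialect.
* Dummy coding uses the first-observed level as reference; numeric
  covariates are mean-centered by default, 0/1 indicators and grouping
  factors never are; centering values are recorded in the design.
* Non-convergent columns (rare) are interpolated linearly between
  converged neighbours for smoothing and excluded from covariance
  estimation; more than 20% non-convergence aborts with advice to
  simplify the model.
* The jackknife df needs at least 3 levels of the coarsest grouping
  factor; with fewer (or no random effects) the multiplier falls back to
  Gaussian.
* With `lambda = "auto"`, GCV occasionally undersmooths pure-noise
  curves (selecting a mild penalty instead of the grid maximum in
  roughly a third of noise replicates), and its selection optimism
  slightly inflates band error rates — the reason it is not the default.
* The moment equations use the OLS hat as a proxy for the per-column GLS
  hat; for strongly unbalanced designs with large variance ratios this
  approximation, and the per-column case deletion under missingness, are
  the main known sources of residual bias.
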