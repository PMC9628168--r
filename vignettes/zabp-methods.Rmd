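---
title: "Zero-augmented beta-prime multilevel models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zero-augmented beta-prime multilevel models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Semi-continuous outcomes — yearly pharmaceutical expenditure per person,
medical costs, alcohol consumption — combine a point mass at exactly zero
with a heavily right-skewed continuous positive part. Gaussian models are
wrong twice over (the spike and the skew), and log-transforming the positive
part trades interpretability for an awkward error structure. When such data
are also nested (subjects in cities in provinces), within-cluster
correlation must be carried by random effects, and correlation *between* the
occurrence process and the magnitude process matters: ignoring it biases the
magnitude model.

`zabp` implements a Bayesian two-part (hurdle) mixed-effects model for
three-level semi-continuous data with a beta-prime positive part (the
ZABP-RE model) and a gamma comparator (ZAG-RE), plus everything needed to
evaluate them: MCMC estimation, convergence diagnostics, model-comparison
criteria, synthetic-data generation, and a replicated simulation-study
harness.

## The model

Subject $k$ in city $j$ of province $i$ has response $y_{ijk} \ge 0$ and
indicator $\omega_{ijk} = I(y_{ijk} > 0)$ (threshold exactly zero; no
epsilon).

**Part I (occurrence).** $\omega_{ijk} \sim \mathrm{Bernoulli}(\tau_{ijk})$
with
$\mathrm{logit}(\tau_{ijk}) = X_{1ijk}'\alpha + p_{1i} + c_{1ij}$.

**Part II (magnitude).** Conditional on $y_{ijk} > 0$,
$y_{ijk} \sim \mathrm{BP}(\mu_{ijk}, \psi)$ with
$\log(\mu_{ijk}) = X_{2ijk}'\beta + p_{2i} + c_{2ij}$.

The beta-prime (inverted beta) density in mean–precision form is
$$
f(y \mid \mu, \psi) = \frac{y^{\mu(\psi+1)-1}\,
(1+y)^{-[\mu(\psi+1)+\psi+2]}}{B(\mu(1+\psi),\, \psi+2)}, \qquad y > 0,
$$
with $E(Y) = \mu$ and $\mathrm{Var}(Y) = \mu(1+\mu)/\psi$: for a fixed mean,
larger $\psi$ means smaller variance. It is the classical two-shape
beta-prime with shapes $(\mu(\psi+1),\ \psi+2)$, so the second shape always
exceeds 2 and the mean of the classical form always exists. The comparator
family is a mean–shape gamma, $E(Y)=\mu$, $\mathrm{Var}(Y)=\mu^2/\psi$ — a
parameterization we chose (none is stated for the comparator) so both
families share the log-link mean and a single positive dispersion-like
parameter, making them one-line swappable.

**Random effects.** Each level carries a bivariate normal pair linking the
two parts, $(p_{1i}, p_{2i}) \sim N_2(0, \Sigma_1)$ and
$(c_{1ij}, c_{2ij}) \sim N_2(0, \Sigma_2)$, with unstructured positive
definite $2\times 2$ covariances. A reduced mode (`correlated_re = FALSE`,
or `constant_tau = TRUE`) uses independent scalar effects in the magnitude
part only — the configuration of the simulation design.

**A dropped error term.** Early formulations of this model class carry a
subject-level normal error $e_{ijk}$ inside the Part II predictor, a
leftover of the log-normal two-part tradition. A normal error inside the
beta-prime mean is incompatible with the BP likelihood, and the final fitted
model omits it; we implement Part II as a pure BP/gamma GLMM with level-2
and level-3 effects only, and there is no $\sigma_e$ parameter anywhere.

## Priors

Survey-scale defaults (`zab_priors()`): $\alpha, \beta \sim N(0, 10^4)$
componentwise, $\psi \sim \mathrm{IG}(0.01, 0.01)$, and
$\Sigma_\ell \sim \mathrm{IW}(0.01 I_2,\ 2)$. The source notation writes the
inverse-Wishart on $\Sigma^{-1}$; we read it as an inverse-Wishart on
$\Sigma$ (equivalently a Wishart on the precision), the only reading that
yields the conjugate Gibbs update the estimation strategy relies on.
Simulation-design priors (`zab_priors_sim()`): coefficients $N(0, 100)$,
$\psi \sim \mathrm{Gamma}(0.01, 0.01)$,
$\sigma^2_\ell \sim \mathrm{IG}(0.01, 0.01)$, $\tau \sim U(0,1)$.
Sensitivity analyses (e.g. $\psi \sim \mathrm{Gamma}(k,k)$,
$k \in \{0.001, 0.1\}$; coefficient precisions 0.1/0.25/0.001) are expressed
purely through these hyperparameters — no special interface.

## MCMC

`zab_fit()` runs Metropolis-within-Gibbs per chain:

* $\alpha$, $\beta$: componentwise Gaussian random-walk Metropolis;
* $\psi$: random-walk on $\log\psi$ with the Jacobian correction, support
  truncated to $|\log\psi| < 300$ (beyond that `exp()` under/overflows; under
  the near-flat small-$\psi$ tail of a Gamma(0.01, 0.01)-type prior the
  truncation is numerically negligible);
* random effects: per-cluster random-walk Metropolis, bivariate in
  correlated mode — necessary because the BP likelihood breaks conjugacy for
  location effects;
* $\Sigma_1, \Sigma_2$: conjugate inverse-Wishart Gibbs given the effects;
  independent-mode variances: conjugate inverse-gamma; constant $\tau$:
  conjugate Beta given the zero/nonzero counts.

Proposal scales are adapted during burn-in by Robbins–Monro toward a 0.35
acceptance rate (per coefficient and per cluster) and frozen afterwards.
Starting values come from a crude two-stage fit (logistic regression for
Part I, log-linear least squares on the positive subset for Part II,
method-of-moments $\psi$), independently jittered per chain to get widely
dispersed initializations. Chain $k$ seeds the R RNG with `seed + k - 1`;
identical data, settings and seed reproduce draws bitwise.

The default schedule (2 chains of 20,000, burn-in 10,000, thin 10) is a
desk-scale reduction of the published one (2 chains of 200,000, burn-in
100,000, lag 100 — itself only ~1,000 retained draws per chain); the full
schedule is a `zab_control()` call away. Convergence is monitored by
split-chain $\widehat{R}$ (`gelman_rubin()`), and `summary()` reports
pooled means, SDs, equal-tail 95% credible intervals and a significance
flag (interval excludes zero).

### Numerical choices

* All densities are computed in log space via `lgamma()`; the beta function
  is never evaluated directly (it overflows at moderate $\psi$).
* Linear predictors are capped at $\pm 40$ before exponentiation.
* $\tau$ is bounded away from $\{0,1\}$ by $10^{-12}$ inside logs.
* A proposal whose log-posterior difference evaluates to NaN (out of
  support) is rejected, never silently accepted.
* $\psi$ is weakly identified when true dispersion is extreme: the BP tail
  exponent is $2+\psi$, so distinguishing $\psi = 0.1$ from $\psi \to 0$
  needs far more positive observations than a desk-scale dataset carries.
  With the near-flat Gamma(0.01, 0.01) prior the $\psi$ posterior then
  spreads over many log-decades toward zero. This is a property of the
  model-prior pair, not of the sampler — the quadrature cross-check below
  confirms the sampler tracks the exact posterior.

## Model comparison

`pointwise_loglik()` evaluates the hurdle mixture density
$(1-\tau)^{1-\omega}[\tau f(y\mid\mu,\psi)]^{\omega}$ per subject and
retained draw. The predictive density is defined with random effects
integrated out; no integration scheme is prescribed, so by default we
evaluate conditionally on each draw's sampled effects — standard practice
for CPO computations in BUGS-style hierarchical output — with
`marginal = TRUE` offering a Monte-Carlo marginalization (fresh effects
drawn from $N(0, \Sigma^{(m)})$) for the stricter reading.

From one matrix, four criteria: DIC$_3$ ($\bar D + p_D$, plug-in deviance at
the posterior means of everything including random effects — the plug-in is
otherwise undefined in a hierarchical model), LPML (log-space harmonic-mean
CPOs), WAIC ($2p_{\mathrm{WAIC2}} - 2\,\mathrm{LPPD}$, exactly, by
construction), and importance-sampling LOO-CV with reciprocal-density
weights truncated at $\sqrt{K}\bar w$ (untruncated, LOO $= -2\,$LPML
algebraically; the identity is kept testable via `truncate = FALSE`).
All per-subject reductions use log-sum-exp; full density matrices are never
exponentiated.

## What the generators emulate — and what they don't

`sim_design()` states the estimator-evaluation world: constant
$\tau = 0.2$, one Bernoulli(0.8) covariate, $\beta_0 = 2$, $\beta_1 = 1.5$,
$\sigma_p^2 = 1.8$, $\sigma_c^2 = 2.3$, $\psi = 0.1$ (BP) or $1$ (gamma).
The design leaves the within-level sizes unstated; we fixed $n_i = 2$ cities
per province and $m_{ij} = 5$ subjects per city — the smallest sizes that
keep all three levels non-trivial while letting the stated $n$ (number of
provinces) drive the asymptotics — both configurable. "Sample size $n$"
counts level-3 units, since that is what the top-level index runs over.

`pe_like_design()` emulates the *structure* of the withheld expenditure
survey: 31 provinces, 429 cities, six covariates (log-normal cost-like
totals and coverage, shifted-Poisson counts, truncated-normal age, Bernoulli
sex), correlated bivariate effects, a 16.1% target zero fraction (the Part I
intercept is solved against the realized covariates and effects so the
expected zero fraction hits the target exactly), and a heavy right tail.
The covariate laws are fixed, documented stand-ins; no attempt is made to
match the survey's descriptive moments beyond the zero fraction. A green
integration test on this generator therefore establishes that the machinery
recovers a world *like* the survey — not the survey's published estimates,
whose data are not deposited.

## The simulation study

`run_study()` wraps replicated simulate–fit–score cycles and reports, per
(generating family, fitted family, $n$, parameter): relative bias
$\frac{1}{R}\sum_r (\hat\theta_r - \theta)/\theta$ (an error, not a silent
fallback, when $\theta = 0$), MSE, 95% coverage (closed intervals: a truth
on the bound counts), and the convergence rate (share of fits with all
$\widehat{R} < 1.1$). Replicate seeds derive deterministically from one
master seed. Dispersion parameters are flagged non-comparable across
families (different scales). The acceptance suite runs this at a reduced
scale — 20 replicates for the recovery criterion, 10 cross-fit replicates
for model selection, ~500 pooled draws per fit — sized to a single-CPU test
budget; the asymptotics being probed are in $n$, not in chain length or
replicate count, but small-replicate noise is the price (see limitations).

Reported criterion magnitudes in the source's simulation summary
(10^6–10^8 deviance-scale values against ~10^3 LPML for the same fits) are
mutually inconsistent, so only the model-*ranking* property — all four
criteria prefer the generating family in a majority of replicates — is
asserted.

## Known limitations

* Three levels, fixed; the independence switch covers the reduced design but
  no deeper nesting.
* No covariate-dependent $\psi$, no skew-normal random effects (both noted
  as extensions in the source's discussion; out of scope here).
* LOO uses plain truncated importance sampling, not Pareto-smoothed
  fitting of the weight tail; subjects whose largest normalized weight
  exceeds 0.5 are flagged instead.
* With 20 replicates, the relative-bias monotonicity probed by the
  acceptance suite sits near the Monte-Carlo noise floor when the estimator
  is nearly unbiased at both sample sizes; MSE monotonicity is the robust
  signal at this scale.
* Covariate centering is a flag (`center = TRUE`) defaulting to off; whether
  the published analysis centered is ambiguous in the source.
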