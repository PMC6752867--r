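---
title: "Prepaid likelihood-free estimation: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prepaid likelihood-free estimation: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prepaid)
```

## The idea

Simulation-based inference for models without a tractable likelihood
(chaotic population dynamics, individual-based community assembly, and the
like) normally restarts an expensive Monte-Carlo search for every data set.
This package implements the *prepaid* alternative: chart the entire bounded
parameter space **once**, by simulating long runs at a quasi-random set of
parameter vectors and compressing them into summary statistics; then answer
every subsequent estimation request by querying that database — nearest
neighbours under a synthetic likelihood, local surrogate interpolation with
global optimization, or grid-based approximate Bayesian computation (ABC).
The database (a `prepaid_grid`) stores, per parameter vector $\theta_p$:

* the long-run statistic mean $\hat\mu_{\theta}$,
* statistic covariances $\hat\Sigma_{\theta,T}$ estimated from contiguous
  splits of the long run at a few stored lengths $T$,
* optionally a bank of raw split statistics for ABC.

Everything downstream is built on the synthetic log-likelihood
$$
\ell_s(\theta) \;=\; -\tfrac12\,(s^{\mathrm{obs}}-\hat\mu_\theta)^\top
\hat\Sigma_\theta^{-1}(s^{\mathrm{obs}}-\hat\mu_\theta)
\;-\;\tfrac12\log\lvert\hat\Sigma_\theta\rvert ,
$$
i.e. a Gaussian working likelihood on summary statistics, with the
$2\pi$ constant dropped (it cancels in every comparison). Because the
stored statistics are averages, a covariance stored at length $T_{\mathrm{pre}}$
transfers to an observed length $T_{\mathrm{obs}}$ by the exact affine map
$\hat\Sigma_{\theta,T_{\mathrm{obs}}} =
(T_{\mathrm{pre}}/T_{\mathrm{obs}})\,\hat\Sigma_{\theta,T_{\mathrm{pre}}}$,
with the stored length chosen nearest to $T_{\mathrm{obs}}$ on the log
scale.

## Models shipped

**Ricker.** $y_t \sim \mathrm{Pois}(\phi N_t)$,
$N_{t+1} = r N_t e^{-N_t + e_t}$, $e_t \sim N(0,\sigma^2)$. Parameters:
growth rate $r$, process noise $\sigma$, observation scaling $\phi$.
Default box $r\sim U(1,90)$, $\sigma\sim U(0.05,0.7)$, $\phi\sim U(0,20)$
(a wider, log-scaled box is available for data outside this range). The
initial state and burn-in are not part of the model statement; we set
$N_0=1$ and discard 50 steps, which removes the transient while staying in
the stationary regime. Poisson sampling uses the current hidden state
*before* the next-step noise enters the recursion. Ten statistics: mean,
proportion of zeros (a percentage, hence comparable across series
lengths), autocovariances at lags 1–5, and the three OLS coefficients of
$y_t^{0.3}$ on $\{1, y_{t-1}^{0.3}, (y_{t-1}^{0.3})^2\}$. The
ordered-difference cubic regression sometimes used with this model needs
the observed values and therefore cannot be precomputed; it is excluded.
The quadratic autoregression is read literally as OLS on the lagged value
and its square; a degenerate (constant) series yields coefficients
$(\overline{y^{0.3}}, 0, 0)$.

**Trait community.** A local community of $J$ individuals from a regional
pool of $S$ species evenly spaced on the trait axis $[0,100]$. Each step
one local individual dies uniformly; with probability $I/(I+J+1)$ it is
replaced by a uniform immigrant species, otherwise by a local offspring
chosen proportionally to the filter
$F(u) = 1 + A\,e^{-(u-h)^2/(2\sigma_f^2)}$. Estimation box (natural logs):
$\log I\sim U(3,5)$, $\log A \sim U(\log 0.1, \log 5)$, $h\sim U(-25,125)$,
$\log\sigma_f\sim U(\log 0.5,\log 25)$. Statistics per snapshot: richness,
Shannon entropy, trait mean, trait skewness; a series of snapshots is
summarized by averaging. Snapshots are recorded every `thinning` deaths
(default $J$ deaths at the standard configuration) because consecutive
deaths barely move the statistics. The model statement is silent on
initialization; we initialize uniformly from the pool and discard a
transient of $10J$ deaths, long enough for richness to equilibrate at the
configurations used here. Parent sampling is implemented by rejection
against $F_{\max} = 1+A$, making each death O(1), which is what allows
grid construction at realistic sizes on one CPU.

**Toy normal.** $y_i \sim N(\mu, s^2)$ with $s$ known; statistic either
$\bar y$ (situation 1, sufficient and linear in $\mu$) or $\bar y^2$
(situation 2, quadratic). Situation 2 identifies $\mu$ only up to sign, so
its grids are clipped to the nonnegative half-line; without clipping,
neighbour selection mixes both branches and the inverted regression slope
collapses. The toy model is the analytic anchor of the package: the
estimator $\hat\mu = (\bar y - \hat\beta_0)/\hat\beta_1$ obtained by
inverting the local regression of simulated statistics on $\mu$ has
closed-form bias
$-\alpha\,12 s^2/(T_{\mathrm{sim}}\Delta^2 N^3)$ (with $\alpha$ the
systematic offset of the selected neighbourhood) and variance
$$
\frac{s^2}{T_{\mathrm{obs}}} + \frac{s^2}{T_{\mathrm{sim}}N}
 + \frac{12 s^2\,E\!\left[(\mu-M_\mu)^2\right]}{T_{\mathrm{sim}}\Delta^2N^3}
 + \frac{24 s^4}{T_{\mathrm{obs}}T_{\mathrm{sim}}\Delta^2N^3}
 + \frac{144 s^6}{T_{\mathrm{obs}}T_{\mathrm{sim}}^2\Delta^4N^6}.
$$
(The published final line of this expansion carries an $N^4$ exponent on
the third term; recombining the penultimate line of the same derivation
gives $N^3$, which is what we implement and what the simulations match.)
The leading term is the classical $s^2/T_{\mathrm{obs}}$; all others vanish
with the prepaid simulation effort, but grow when the grid gap $\Delta$
shrinks at fixed neighbourhood size $N$ — interpolation on too small a
lever arm. For the quadratic statistic an opposing error appears at large
$\Delta$ (linear fit to a curved response), producing the interior optimum
that `toy_rmse_surface()` exhibits.

## Estimators

* **SLMLGrid** — arg-max of $\ell_s$ over grid rows; ties break to the
  lowest row index for reproducibility. Its accuracy floor is the grid
  gap, `expected_grid_gap(space, omega)` $= \mathrm{range}/\Omega^{1/K}$
  per dimension.
* **SLMLSVM / SLMLLin** — per-statistic surrogate $\hat f:\theta\mapsto s$
  fitted on the 100 nearest neighbours (tuned RBF least-squares SVM, or
  OLS), then differential evolution maximizes the interpolated
  $\ell_s^{PP}$ inside the neighbours' bounding box. Predictions are
  clamped to each statistic's admissible range (a proportion stays in
  $[0,1]$). Part of the population is seeded with the neighbour rows, so
  the returned objective never falls below the best grid row's.
* **SLMAPGrid** — arg-max of log-prior plus $\ell_s$; a flat prior reduces
  it to SLMLGrid. Priors are box-mapped Beta products or any object with a
  `logpdf`.
* **Constrained estimation** — several experimental conditions sharing
  parameters: per-condition candidate pools (top 200 rows), a
  product-normal equality penalty of width $\sigma_{\mathrm{prior}}$ on the
  working scale (unnormalized — the arg-max is invariant), exhaustive
  combination search for two conditions, then shared parameters replaced by
  their cross-condition mean so the constraint binds exactly. The width is
  tuned by simulated recovery (`tune_sigma_prior()`); widths near zero
  collapse all conditions onto one grid row (even unshared parameters
  become equal), which the tuner detects and discards.
* **Bootstrap intervals** — parametric bootstrap at the estimate,
  re-estimated by SLMLGrid, percentile intervals. When the first 100
  bootstrap estimates hit fewer than 50 unique rows the grid is too coarse
  for the bootstrap distribution (expected at large $T_{\mathrm{obs}}$) and
  every replicate is re-estimated by differential evolution on the
  surrogate of the original observation.
* **SLPMGrid** — posterior mean over grid rows with weights
  $\propto L_s$, recentred by the maximum log-weight before
  exponentiation so finite inputs cannot underflow.
* **ABCPMGrid** — restrict to the smallest set of rows carrying 99.9% of
  the normalized synthetic-likelihood mass, pool the covariance $W_Q$ of
  their banked statistics, keep the 1000 bank samples with the smallest
  Mahalanobis distance to $s^{\mathrm{obs}}$; their source parameters are
  the posterior. A length mismatch with the stored bank is corrected by
  rescaling the *parameter draws* about their mean so the posterior
  covariance gains the factor $T_{\mathrm{pre}}/T_{\mathrm{obs}}$ — mean
  preserved exactly.
* **ABCPMSVM** — refines ABCPMGrid between grid rows: Ward-cluster the
  100 rows contributing most kept samples (≤50 rows per cluster, padded to
  ≥20 with the nearest rows), per cluster fit an LS-SVM surrogate and the
  minimum-volume enclosing ellipse (Khachiyan, tolerance $10^{-5}$,
  inflated marginally so every defining point is inside; degenerate sets
  fall back to a bounding box); iterate: sample 1000 parameters uniformly
  in the ellipse, predict statistics, translate the nearest row's bank by
  the predicted shift, score all (parameter, sample) pairs, keep the 5000
  best pairs and refit the ellipse — until the worst kept distance
  improves by less than $10^{-3}$ relatively (cap 50 iterations). Because
  the kept pool always contains the previous kept pairs, the worst kept
  distance is non-increasing once the pool saturates. Draws are weighted
  by their cluster's ellipse volume (the uniform prior over each sampled
  region); duplicated parameters in the final sample are intentional.

## Numerical choices

* Covariances are ridged with $10^{-8}\times$ mean diagonal before
  inversion/Cholesky; near-singular statistic sets occur at extreme
  parameters (e.g. a noise-free fixed point).
* Per-row inverse covariances and log-determinants are cached per stored
  length, so evaluating all $\Omega$ synthetic log-likelihoods is a single
  matrix product.
* Differential evolution: rand/1/bin, population $15K$, $F=0.8$,
  $CR=0.9$, 200 generations, spread tolerance $10^{-8}$ — standard robust
  defaults; the spec of the optimizer is otherwise not prescribed by the
  method.
* LS-SVM tuning: exact leave-one-out error on a 5×5 log grid over
  regularization ($10^{-1}\ldots10^{7}$) and RBF bandwidth (median
  pairwise distance × $2^{-2}\ldots2^{2}$), per statistic, on
  standardized inputs and outputs.
* Weighted posterior quantiles use cumulative-midpoint plotting positions
  rescaled to $[0,1]$: under equal weights this is exactly `quantile(...,
  type = 7)`; mass concentrated on one draw collapses the interval onto
  it.
* All randomness flows through R's RNG (also inside the C++ simulators),
  and every long-running routine derives per-unit seeds from a master seed
  via `derive_seed()`, so builds are independent of evaluation order and
  every CLI output is bit-reproducible given `--seed`.

## What the synthetic-data studies do and do not establish

The test suite rebuilds every fixture from code, at sizes reduced from the
published full-scale studies (which took ~20 core-days of grid building)
so the whole suite runs in minutes on one CPU: the Ricker recovery study
uses $\Omega = 2000$ points with long runs of $10^5$ (instead of $10^5$
points × $10^7$), the trait study $\Omega = 5000$, $S = 200$, $J = 100$
with shorter snapshot series and a bank rescaled from stored length 100 to
$T_{\mathrm{obs}} = 1000$ (a non-marginal factor-10 covariance correction
that the full-scale protocol avoids by storing longer banks). At these
sizes the *qualitative* claims are preserved and tested — error decreasing
in sample size, surrogate interpolation beating pure nearest neighbour
once the grid gap dominates, constrained estimation beating unconstrained
on shared parameters, ABC refinement beating the raw bank — but the
*absolute* published error tables are not reproducible at desk scale and
are not asserted. A green suite therefore establishes correctness of the
machinery and the direction of every published comparison, not the
published numbers themselves. Residual caveats: the reduced trait bank is
small (tens of splits per row), so grid-ABC posteriors at large
$T_{\mathrm{obs}}$ are intentionally coarse, which is precisely the regime
where the surrogate variant is expected to help; and nearest-neighbour
recovery at reduced $\Omega$ is gap-limited, so a handful of
ridge-degenerate test draws (small growth rate, near-boundary noise)
dominate the squared error of the interpolated Ricker estimator — the
median error is an order of magnitude smaller.

## Known limitations

* The grid container is a versioned RDS file; it is self-describing and
  lossless but R-specific.
* The constrained-search step is exhaustive only for two conditions;
  more conditions use coordinate ascent over pools.
* LS-SVM surrogates are fitted independently per statistic; correlated
  prediction errors are not modelled (they partly cancel in the
  Mahalanobis objective).
* The curse of dimensionality is inherited: grid size grows exponentially
  in the number of parameters; the shipped models have 1, 3 and 4.
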