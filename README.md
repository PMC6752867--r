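# prepaid — likelihood-free parameter estimation from a precomputed grid

Simulation-based models in ecology, epidemiology and the behavioural
sciences — chaotic population dynamics, individual-based community
assembly, accumulator models — often have no tractable likelihood, and the
standard remedies (synthetic-likelihood MCMC, sequential ABC) re-run an
expensive Monte-Carlo search for *every* data set. `prepaid` implements the
alternative of paying the simulation cost **once**: chart the bounded
parameter space with quasi-random (Halton) points, simulate one long run
per point, and compress it into summary-statistic means
$\hat\mu_\theta$, per-length covariances $\hat\Sigma_{\theta,T}$ and raw
sample banks. Any subsequent data set is then estimated in seconds from
the stored database, via the synthetic log-likelihood

$$\ell_s(\theta) = -\tfrac12 (s^{obs}-\hat\mu_\theta)^\top
\hat\Sigma_\theta^{-1}(s^{obs}-\hat\mu_\theta)
- \tfrac12\log|\hat\Sigma_\theta|,\qquad
\hat\Sigma_{\theta,T_{obs}} = \tfrac{T_{pre}}{T_{obs}}\hat\Sigma_{\theta,T_{pre}}.$$

Estimators: nearest grid neighbour (`estimate_slml_grid`), tuned LS-SVM /
linear surrogate interpolation optimized by differential evolution
(`estimate_slml_svm`), MAP with arbitrary priors (`estimate_map`),
cross-condition equality constraints with a tuned product-normal penalty
(`estimate_constrained`, `tune_sigma_prior`), parametric-bootstrap
confidence intervals with an automatic surrogate fallback
(`parametric_bootstrap_ci`), and three Bayesian variants: grid posterior
means (`posterior_mean_grid`), bank-based ABC (`abc_posterior_grid`) and
ellipse-refined surrogate ABC (`abc_posterior_svm`). Shipped models: the
Ricker map with Poisson observations, a trait-filtered neutral community
model, and an analytically solvable toy-normal study
(`toy_replicates`, `toy_rmse_surface`). A study harness
(`make_test_set`, `run_recovery_study`, `run_coverage_study`) reproduces
recovery/coverage protocols at configurable scale.

## Worked example (Ricker)

```r
library(prepaid)

model <- ricker_model()                       # r ~ U(1,90), sigma ~ U(0.05,0.7), phi ~ U(0,20)
spec  <- grid_spec(model$space, omega = 2000, t_sim = 1e5,
                   t_prepaid = c(100, 1000), m = 0, seed = 1)
grid  <- build_grid(model, spec)              # ~1 minute, paid once

y     <- simulate_ricker(c(r = 44.7, sigma = 0.3, phi = 10), T = 1000, seed = 99)
s_obs <- summarize_ricker(y)                  # 10 statistics

estimate_slml_grid(grid, s_obs, t_obs = 1000)
#> prepaid_estimate (SLMLGrid)
#>        r    sigma      phi
#> 40.28500  0.42984 10.43200
#>   objective: -12.92524

set.seed(7)
est <- estimate_slml_svm(grid, s_obs, t_obs = 1000)
est
#> prepaid_estimate (SLMLSVM)
#>        r    sigma      phi
#> 44.27900  0.28561 10.05300
#>   objective: -5.703647

ci <- parametric_bootstrap_ci(grid, model, est$theta_hat, t_obs = 1000,
                              B = 200, s_obs = s_obs, seed = 7)
round(ci$interval, 3)
#>        lower  upper
#> r     40.647 47.950
#> sigma  0.219  0.346
#> phi    9.786 10.318
```

The true parameters were (44.7, 0.3, 10). The nearest grid row is off by
roughly the grid gap (`expected_grid_gap(model$space, 2000)` ≈ 7.1 in `r`
at this reduced grid size); surrogate interpolation between the 100
nearest rows recovers the truth to a fraction of the gap, and the 95%
bootstrap interval covers it in every coordinate. At the full published
grid size (10^5 points, runs of 10^7) the same pipeline attains
gap-of-the-grid accuracy in well under a second per data set.

## Command line

A single dispatcher (also installed as `exec/prepaid`):

```sh
Rscript -e 'prepaid::prepaid_cli()' build-grid --model ricker \
    --out ricker.rds --omega 2000 --tsim 100000 --tprepaid 100,1000 --seed 1
Rscript -e 'prepaid::prepaid_cli()' estimate --grid ricker.rds \
    --data counts.txt --method svm --tobs 1000 --seed 7
Rscript -e 'prepaid::prepaid_cli()' bootstrap --grid ricker.rds \
    --data counts.txt --B 1000 --seed 7
```

Count series are one integer per line; community snapshots are CSV
(`species_index, trait, abundance[, snapshot]`); results are JSON.
Every output is bit-reproducible given `--seed`.

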