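# lcls — latent class location-scale regression for longitudinal data

Behavioural diary studies (daily calorie intake, mood ratings, activity
logs) often hide two kinds of subgroup structure at once: groups of
subjects whose **mean trajectories** differ, and groups whose
**within-subject variability** — how erratic each subject is around their
own trajectory — differs and drifts over time. `lcls` fits location-scale
regressions with separate latent classes in both parts. Conditional on
subject *i*'s location class ℓ and scale class *s*,

    Y_ij | L_i = ℓ  =  β0_ℓ + β1_ℓ t_ij + ε_ij,
    Var(ε_ij) | S_i = s  =  exp(τ0_s + τ1_s t_ij),

with independent multinomial memberships π^loc and π^sc. The subject-level
marginal likelihood sums the L×S class grid, so the package provides:

* the mixture likelihood, Bayes-rule posterior memberships, modal
  classification and relative-entropy summaries (`marginal_loglik`,
  `posterior_memberships`, `assign_classes`, `entropy_summary`);
* two estimation engines: an adaptive Hamiltonian Monte Carlo sampler with
  flat priors and the two-stage warm-start protocol (`fit_bayes`), and a
  fast multi-start maximum-likelihood engine with observed-information
  intervals (`fit_map`);
* class enumeration over an (L, S) grid by Pareto-smoothed
  importance-sampling leave-one-subject-out cross-validation with the
  "last improvement ≥ 4 SE" rule (`psis_loo`, `compare_grid`);
* a seeded synthetic-data generator for balanced latent-class designs and
  a diary-style observation filter (`simulate_lcls`, `smart_filter`);
* simulation scoring — label alignment, bias, interval width, coverage and
  classification rates (`align_labels`, `evaluate_replications`);
* a command-line pipeline (`inst/cli/lcls.R`, subcommands `simulate`,
  `fit`, `select`, `classify`, `evaluate`).

It is aimed at biostatisticians and behavioural researchers who want
interpretable subject subgroups based on *consistency* as well as level.

## Worked example

Simulate a 100-subject benchmark dataset (three location and three scale
classes, 12 weekly periods, 10 observations per week), fit the 3×3 model
with the maximum-likelihood engine, and summarize:

```r
library(lcls)
sim <- simulate_lcls(scenario1_spec(seed = 42, n_subjects = 100))
fit <- fit_map(sim$data, lcls_model(3, 3), fit_config(engine = "map", seed = 1))
print(fit)
#> lcls fit (map engine): 3 location x 3 scale classes, 100 subjects
#>   converged: TRUE
#> lcls parameter set (3 location x 3 scale classes)
#> location (beta0, beta1), pi:
#>       beta0   beta1     pi
#> loc1 6.9118 -0.0191 0.3897
#> loc2 7.1462 -0.0095 0.2994
#> loc3 7.3477 -0.0056 0.3109
#> scale (tau0, tau1), pi:
#>           tau0   tau1     pi
#> scale1 -2.3821 0.0181 0.3900
#> scale2 -1.6582 0.0408 0.3100
#> scale3 -0.6815 0.0083 0.3001
```

The estimates recover the generating values (β0 = 6.92/7.15/7.38,
τ0 = −2.41/−1.74/−0.78): location classes are ordered by baseline level,
scale classes by baseline consistency, with class 3 about five times as
variable as class 1 at week 0. Classification is nearly crisp:

```r
entropy_summary(membership(fit))
#> relative entropy - location: 0.978 | scale: 0.999
```

For a log-scale outcome the slopes are multiplicative trends;
`report_transforms` converts them to percent change over the study span
(time coded 0–11) and to baseline within-subject variances:

```r
report_transforms(fit$estimate, elapsed_time = 11)
#> location classes (percent decrease over 11 time units):
#>  class beta0  beta1 pct_decrease
#>      1 6.912 -0.019       18.974
#>      2 7.146 -0.010        9.926
#>      3 7.348 -0.006        6.011
#> scale classes (baseline within-subject variance exp(tau0)):
#>  class   tau0  tau1 baseline_ws_variance
#>      1 -2.382 0.018                0.092
#>      2 -1.658 0.041                0.190
#>      3 -0.681 0.008                0.506
```

So the lowest-intake class cut intake by ~19% over the study while the
highest class barely changed — the kind of contrast that motivates
class-tailored interventions. For Bayesian inference swap in
`fit_bayes()` (four chains × 2000 iterations with 500 warm-up by
default, split-chain R-hat convergence flags), and choose L and S with
`compare_grid()`.

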