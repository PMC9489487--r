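# brainsem

Collider-aware inference for comparative analyses that use **relative
brain size** — brain size beyond the allometric expectation for body
size — either as a response or as a predictor variable.

## The problem

Comparative studies routinely "control for allometry" by putting
absolute brain size and body size together in a multiple regression.
Whether that works depends on the causal role of relative brain size:

* **Case I — relative brain size as response.** Body size and a third
  trait *z* (sociality, say) both cause brain size. There is no open
  back-door path, so the regression
  `brain ~ body + z` estimates both effects correctly; body size is
  included only to absorb allometric variation.

* **Case II — relative brain size as predictor.** Body size and
  relative brain size both cause *z* (longevity, say), and absolute
  brain size is the *sum* of the allometric part and the relative part:
  `brain = β_body · body + rel`. Absolute brain size is then a
  **collider** — a variable caused by two others. Conditioning on it in
  `z ~ body + brain` opens a back-door path through body size, and the
  fitted body coefficient converges not to the true direct effect
  γ_body but to `γ_body − β_body · γ_brain`. With unit effects that is
  0; with a strong brain effect it is negative. No multiple regression
  on these variables can repair this.

The remedy implemented here is a Bayesian **structural equation model
(SEM)** in which brain size is simultaneously a response (of body size)
and, through relative brain size, a predictor of *z*:

```
body_i  ~ Normal(α_body, σ_body)
brain_i ~ Normal(μ_brain,i, σ_brain)   μ_brain,i = α_brain + β_body · body_i
z_i     ~ Normal(μ_z,i, σ_z)           μ_z,i = α_z + γ_body · body_i
                                               + γ_brain · (brain_i − μ_brain,i)
α ~ Normal(0, 1)   β, γ ~ Normal(0, 1)   σ ~ Exponential(1)
```

Relative brain size, `brain_i − μ_brain,i`, is recomputed at every
posterior draw, so its uncertainty propagates into γ_brain — unlike the
historical two-step "regress, take residuals, regress again" practice.

The package provides:

* `sim_scenario()` / `simulate_dataset()` / `make_replicates()` —
  seeded generative simulators for both cases (plus a confounded
  variant of case I with a direct body → z path);
* `fit_linear()` — OLS with classical standard errors, and
  `case2_collider_expectation()`, the closed-form probability limits of
  the collider-biased coefficients;
* `fit_bayes_linear()` / `fit_sem()` — JAGS-backed posterior sampling
  (4 chains, 1000 warmup + 1000 sampling by default) with Rhat,
  effective-sample-size monitoring and an automatic extended-warmup
  retry;
* `run_experiment()` / `run_preset()` — the Monte-Carlo grid that
  scores every estimator's **bias** (truth − estimate) and **coverage**
  (truth inside estimate ± 2 SE/SD) over replicates;
* `render_estimates_figure()` — density-strip comparison figures with
  the true value as a dashed line.

## Worked example

```r
library(brainsem)

sc <- sim_scenario("case2", n_species = 100, n_replicates = 20, base_seed = 1)
d  <- simulate_dataset(sc, 1)      # truth: beta_body = gamma_body = gamma_brain = 1

fit_dataset_ols(d)                 # the collider in action
#> <linear_fit> z ~ body + brain  (n = 100)
#>             estimate      se
#> (Intercept)  0.01447 0.09236
#> body         0.11330 0.12510
#> brain        1.03400 0.09385
#> residual SD: 0.9222

fit_sem(d)$posterior_mean[c("gamma_body", "gamma_brain")]
#> gamma_body gamma_brain
#>      1.019       1.026
```

The OLS body coefficient (0.11 ± 0.13) has collapsed toward the
collider limit γ_body − γ_brain = 0 although the true direct effect is
1; the SEM recovers both effects. The full 20-replicate,
two-case experiment (about 40 s):

```r
run_preset("table1", base_seed = 1)
#>    case_id parameter        model mean_bias sd_bias coverage n_replicates
#> 1    case1      body       linear     -0.01    0.12     0.85           20
#> 2    case1      body bayes_linear      0.00    0.12     0.85           20
#> 3    case1         z       linear     -0.02    0.09     0.95           20
#> 4    case1         z bayes_linear     -0.01    0.09     0.95           20
#> 5    case2      body       linear      1.04    0.18     0.00           20
#> 6    case2      body bayes_linear      1.03    0.17     0.00           20
#> 7    case2      body          sem      0.03    0.15     0.90           20
#> 8    case2     brain       linear     -0.04    0.13     0.95           20
#> 9    case2     brain bayes_linear     -0.03    0.12     0.95           20
#> 10   case2     brain          sem     -0.03    0.13     0.95           20
```

Reading the table: in case I every model is essentially unbiased with
near-nominal coverage. In case II the linear models' body-size estimate
carries bias ≈ +1 (the whole true effect) and **zero** coverage — the
±2 SE interval around ≈ 0 never contains 1 — while the SEM's body bias
is ≈ 0.03 with 90% coverage. The brain-size effect is estimated well by
every model; it is only the body effect the collider corrupts.

A thin CLI over the same functions ships in `inst/cli/brainsem.R`
(subcommands `simulate`, `fit-ols`, `fit-bayes`, `experiment`,
`report`).

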