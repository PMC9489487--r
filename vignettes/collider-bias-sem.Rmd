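---
title: "Relative brain size as a predictor: collider bias and a structural equation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative brain size as a predictor: collider bias and a structural equation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The two causal structures

Comparative biologists rarely care about absolute brain size; the
quantity of interest is *relative* brain size — the brain tissue a
species carries beyond the allometric expectation for its body size.
All variables here live on the log scale, where allometric effects are
assumed linear, and are simulated standardized (mean 0, SD 1) so the
conclusions do not depend on measurement units.

Two superficially similar study designs have opposite statistical
behaviour.

**Case I: relative brain size as response.** Body size and a third
trait *z* both cause brain size:

\[
\mathrm{body} \sim N(0,1),\quad z \sim N(0,1),\quad
\mathrm{brain} \sim N(\beta_{body}\,\mathrm{body} + \beta_z\, z,\ \sigma_{brain}).
\]

No arrow points into *z*, so no back-door path is open and the multiple
regression `brain ~ body + z` estimates \(\beta_z\) — the effect of *z*
on relative brain size — without bias. Body size is included purely to
absorb allometric variance.

**Case II: relative brain size as predictor.** The latent relative
brain size `rel` and body size jointly determine both the observable
brain size and the outcome *z*:

\[
\mathrm{body} \sim N(0,1),\quad \mathrm{rel} \sim N(0,1),\quad
\mathrm{brain} = \beta_{body}\,\mathrm{body} + \mathrm{rel},\quad
z \sim N(\gamma_{body}\,\mathrm{body} + \gamma_{brain}\,\mathrm{rel},\ \sigma_z).
\]

Brain size is deliberately the *exact* sum of its two causes — the
package preserves this identity to machine precision — which makes it a
collider. Substituting \(\mathrm{rel} = \mathrm{brain} -
\beta_{body}\,\mathrm{body}\) into the mean of *z* shows what the
regression `z ~ body + brain` actually estimates:

\[
E[z] = (\gamma_{body} - \beta_{body}\,\gamma_{brain})\,\mathrm{body}
       + \gamma_{brain}\,\mathrm{brain}.
\]

The brain coefficient converges to the right value
\(\gamma_{brain}\); the body coefficient converges to
\(\gamma_{body} - \beta_{body}\gamma_{brain}\), which is 0 under unit
effects, positive-but-attenuated when the body effect dominates
(\(\gamma_{body}=2, \gamma_{brain}=0.5 \Rightarrow 1.5\)), and negative
when the brain effect dominates
(\(\gamma_{body}=0.5, \gamma_{brain}=2 \Rightarrow -1.5\)).
`case2_collider_expectation()` returns exactly this algebra and serves
as the analytic oracle for the package's bias tests. No adjustment set
drawn from \{body, brain, z\} fixes the problem; the model class itself
is wrong.

A third simulator, `case1_confounded`, adds a direct body → z path to
case I (`z ~ N(gamma_body * body, sigma_z)`). The strength of that
extra path is a free parameter; its default of 1 keeps it on the same
scale as every other effect in the default scenarios.

## The structural equation model

The remedy is a system of simultaneous regressions in which brain size
is at once response and (through relative brain size) predictor:

\[
\begin{aligned}
\mathrm{body}_i &\sim N(\alpha_{body}, \sigma_{body})\\
\mathrm{brain}_i &\sim N(\mu_{brain,i}, \sigma_{brain}), &
\mu_{brain,i} &= \alpha_{brain} + \beta_{body}\,\mathrm{body}_i\\
z_i &\sim N(\mu_{z,i}, \sigma_z), &
\mu_{z,i} &= \alpha_z + \gamma_{body}\,\mathrm{body}_i
  + \gamma_{brain}\,(\mathrm{brain}_i - \mu_{brain,i})
\end{aligned}
\]

with priors \(\alpha, \beta, \gamma \sim N(0,1)\) and
\(\sigma \sim \mathrm{Exponential}(1)\). The term
\(\mathrm{brain}_i - \mu_{brain,i}\) *is* relative brain size, but it
is recomputed at every iteration of the sampler from the current
\(\alpha_{brain}, \beta_{body}\). Information therefore flows in both
directions — the z-submodel informs the allometric slope and vice
versa — and the uncertainty in the allometric fit propagates into
\(\gamma_{brain}\), which a two-step residual regression discards.

Note \(\sigma_{brain}\) is a real parameter of the model even though
the case II generator builds brain size with no noise term of its own:
the latent `rel` plays the role of the brain submodel's residual, so
the posterior of \(\sigma_{brain}\) concentrates near the SD of
relative brain size (1 under the defaults), not near zero.

## Sampler protocol and diagnostics

All Bayesian models run in JAGS via `rjags` with, by default, 4 chains
of 1000 warmup (adaptation plus burn-in) and 1000 retained iterations —
4000 posterior draws per fit. Chain seeds derive deterministically from
`sampler_config(base_seed=)` through the same stream-splitting function
(`replicate_seed()`) the simulator uses, so an entire experiment is
reproducible from one integer.

Per-parameter split-chain Rhat (via `coda::gelman.diag`) and effective
sample size are computed for every fit. If any Rhat exceeds 1.01 the
model is refitted once with four times the warmup; persistent problems
raise a warning and are recorded in the fit's `diagnostics` and the
experiment `run_log.txt`, and the affected replicate is flagged
(`diagnostics_ok = FALSE`) but not silently dropped. Divergent
transitions are a Hamiltonian-Monte-Carlo concept with no analogue in
JAGS's Gibbs/slice samplers, so the `n_divergent` diagnostic field is
structurally zero here; it is kept so fit reports from this backend
remain comparable with HMC-based refits of the same models. Replicates
where a fit *errors* are excluded from that model's summary with an
explicit reduced count — they are never imputed, and the replicate data
stay identical across models because data generation and model fitting
draw from separate seed streams.

The point estimate for bias is always the posterior mean, and coverage
uses the symmetric interval mean ± 2 posterior SD (matching the ± 2 SE
convention of the frequentist fits), not posterior quantiles.

## Priors

Three named prior sets are built in:

| label | slopes & intercepts | residual SDs | purpose |
|---|---|---|---|
| `default` | Normal(0, 1) | Exponential(1) | mild regularization toward "no effect" |
| `vague` | Normal(0, 10) | Exponential(0.1) | near-flat sensitivity check |
| `informative` | slopes Normal(truth, 0.1) | Exponential(1) | best-case prior information |

The `vague` and `informative` scales are this package's own choices for
"much wider than the data scale" and "tightly centred on the generating
value"; under `informative` the slope locations are resolved from the
simulated dataset's recorded truth at fit time. The informative set
exists to demonstrate a pathology, not a fix: in case II even a prior
centred *on the true body effect* cannot rescue the Bayesian linear
model — the likelihood concentrates away from the truth at rate
\(\sqrt{n}\), so the posterior excludes it anyway. The Bayesian linear
model shares the SEM's default priors, since nothing distinguishes
their regression structure.

## The experiment grid

`run_experiment()` scores, per replicate × model, the case-relevant
parameters (case I: the body and z coefficients of the brain
regression; case II: the body and brain effects on z) and aggregates
mean bias, SD of bias and coverage. Bias is defined as
**truth − estimate**: the collider-biased body estimate (≈ 0, truth 1)
then shows bias ≈ +1, the sign convention used throughout the summary
tables. `summarize_replicates()` is a pure function of the replicate
table, so a summary can always be reproduced from a persisted
`replicates.csv`.

Named presets encode the reported study conditions — `table1` (both
cases, 20 replicates × 100 species, default priors and protocol),
`appendix-n20` / `appendix-n1000` (sample-size sensitivity),
`appendix-vague` / `appendix-informative` (prior sensitivity),
`appendix-strong-body` / `appendix-strong-brain`
(\(\gamma_{body}, \gamma_{brain}\) = (2, 0.5) and (0.5, 2)), and
`appendix-case1-confounded`. The default scenario — 20 replicates,
n = 100, every effect and SD equal to 1 — is the package's reference
condition; the acceptance script runs it unchanged.

```{r, eval = FALSE}
library(brainsem)
ex <- run_preset("table1", base_seed = 1)
ex$summary
```

## What the simulator does and does not emulate

The generator reproduces the *causal* content of the two study designs
under the simplest realistic distributional assumptions: standardized
log-scale traits, linear effects, Gaussian noise, species as
independent draws. It deliberately does **not** simulate phylogenetic
covariance between species, measurement error on any trait, missing
data, or realistic absolute magnitudes of body and brain mass. Passing
tests therefore demonstrate the collider mechanism and its SEM remedy
under ideal sampling; they do not certify the SEM for an empirical
comparative dataset, where phylogenetic non-independence and
measurement error must be added to the model (both are standard
extensions of this SEM but out of scope here).

## Numerical choices and edge cases

* **Seeding.** Replicate r of a scenario uses
  `replicate_seed(base_seed, r)`, a fixed affine map modulo the prime
  \(2^{31}-1\); streams never overlap across replicates or chains, and
  any replicate can be regenerated without generating the others.
* **Exactness.** The case II identity `brain = beta_body * body + rel`
  is preserved bit-for-bit (it is the defining property of the
  collider construction); tests assert `identical()`, not tolerance.
* **Rank deficiency** in `fit_linear()` is an error naming the
  collinear columns. Silently dropping a column — `lm`'s default —
  would hide exactly the structure under study.
* **Degenerate inputs.** Zero-variance traits make the body–brain
  correlation undefined and raise an error; `n_species` below 3 is
  rejected at scenario construction; a zero-row dataset is accepted by
  the Bayesian fitters and yields prior draws, which is how the prior
  implementation is validated.
* **Problem sizes.** Unit tests use shortened chains (2 × 400 + 500)
  where only correctness of the machinery matters; every reported
  number (the 20-replicate summaries, the prior-pathology count) uses
  the full 4 × (1000 + 1000) protocol. Asymptotic checks use single
  datasets of 100 000 species, where Monte-Carlo error is below the
  asserted tolerances.

## Known limitations

* JAGS's Gibbs/slice sampling replaces the No-U-Turn sampler typically
  used for such models; posteriors agree for these linear-Gaussian
  systems, but there is no divergence-based pathology detection, and
  `target_acceptance` is inert with this backend.
* Coverage at 20 replicates has granularity 0.05 and wide binomial
  error (a calibrated 0.95 estimator can legitimately show 0.75–1.00),
  which the acceptance tolerances reflect.
* The SEM assumes the case II causal graph. Fitting it to data from a
  different structure (e.g. z causing brain size) estimates the wrong
  quantity — model choice must come from a DAG of the study system,
  which no software check can replace.
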