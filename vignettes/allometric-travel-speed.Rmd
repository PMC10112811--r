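---
title: "Allometric models of sustained travel speed: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allometric models of sustained travel speed: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allospeed)
```

## The scientific problem

How fast can an animal travel, in a sustained (aerobic) way, given only its
body mass and how it moves? Within each locomotion mode -- flying, running,
swimming -- speed initially increases with body mass: larger animals supply
more metabolic power and move more efficiently per joule. But the largest
animals do not keep getting faster. A mechanistic explanation is that
muscular work inevitably produces heat, larger bodies have more thermal
inertia, and during long locomotion bouts part of the time budget must
effectively be spent dissipating that heat rather than moving. allospeed
implements and compares three process models that encode competing
hypotheses about this heat-dissipation time:

* **metabolic model** (no heat constraint): $v = v_0 M^c$, a power law;
* **constant heat-dissipation model** (mass-independent heat-dissipation
  time $k_0$ per metre): $v = \dfrac{1}{k_0}\dfrac{M^c}{M^c + 1/(v_0 k_0)}$,
  saturating towards $1/k_0$;
* **allometric heat-dissipation model** (heat-dissipation time growing with
  mass as $k_\lambda M^d$ per metre):
  $v = \dfrac{1}{k_\lambda}\dfrac{M^c}{M^{c+d} + 1/(v_0 k_\lambda)}$,
  hump-shaped with an interior maximum.

Here $v$ is realised travel speed (m/s), $M$ body mass (kg), $v_0$ a
mode-specific locomotion rate constant (m s$^{-1}$ kg$^{-c}$), $c$ the
potential-speed exponent, and $d$ the heat-dissipation exponent. All three
models share the same *potential* speed $v_0 M^c$; they differ only in how
much of it can be realised. The hump-shaped curve peaks at
$M^* = (cK/d)^{1/(c+d)}$ with $K = 1/(v_0 k_\lambda)$, so modes with larger
$v_0$ (flying) peak at much smaller masses than slow modes
(running/swimming) -- see `peak_mass()`.

Mechanistically, $c$ is the sum of the exponent $a$ of whole-organism
aerobic power ($\approx$ 0.80--0.97 across taxa) and the exponent $b$ of
maximum locomotion efficiency ($\approx -0.67$), so $c = a + b$ is expected
in $[0.13, 0.30]$ (`exponent_bounds()`). Wider first-principles ranges for
both exponents ($0.01 < c < 0.33$, $0.01 < d < 0.37$) arise from a fuller
biophysical derivation (heat balance via Newtonian cooling, mitochondrial
power density) that this package does not reproduce; `theory_bounds()`
stores such intervals but only the additive $a + b$ bound is computed. The
mechanistic intermediates behind the three closed forms (distance moved,
power input, efficiency, time budgets) are algebraically eliminated into
$v_0$, $k_0$, $k_\lambda$ and are deliberately not represented at runtime.

## Data model and inference

Observations are species-level records $(M_i, v_i, \text{mode}_i)$. The
likelihood is Gaussian on the base-10 log of speed,

$$\log_{10} v_i \sim \mathcal{N}\!\left(\log_{10} f(M_i, \theta),\ \sigma\right),$$

with $f$ the chosen process model; $\sigma$ is therefore in log10 m/s
units. $v_0$ is always estimated independently per locomotion mode (no
pooling); optionally $c$ can vary by mode and the heat-dissipation constant
by realm (aquatic vs terrestrial), giving the eight model structures
reachable through `speed_model()`. No hierarchical partial pooling is used,
and no variational or optimisation-based fitting is offered.

Priors (all overridable through `prior_config()`): half-normal(1) on $c$
and $d$; gamma(1, 0.01) on $v_0$, near-flat over the 0.01--300 m/s range
spanned from slow runners to fast flyers; gamma(1, 1) on $k_0$ and
$k_\lambda$; half-Cauchy(2.5) on $\sigma$. These are weakly informative on
the scales the parameters live on. The test suite includes a ten-fold
prior-broadening sensitivity check and a reduced simulation-based
calibration check (truths drawn from the priors, rank of the truth among
posterior draws uniform).

### Sampler

Fitting uses JAGS through rjags. JAGS selects univariate slice samplers
for this model class from the declared priors, so parameters are sampled
on their natural scales; prototype runs showed this mixes adequately
without a log-scale reparameterisation, which matters more for
gradient-based samplers. The default protocol (`mcmc_config()`) is 3
chains, a 1,500-iteration adaptation phase and 3,000 retained draws per
chain -- 9,000 posterior draws in total. Because univariate slice updates
are more autocorrelated than the trajectories of gradient-based samplers,
sampling thins internally by 3 (9,000 iterations per chain, every third
kept); this keeps the retained-draw count at the protocol's 9,000 while
bulk effective sample sizes on the full-scale problem sit comfortably
above the 1,000 threshold. Initial values are drawn from the central 80%
of each prior and jittered per chain, all reproducibly from one seed; a
pre-flight check aborts with the offending values if any chain would start
at a non-finite likelihood.

Convergence is reported with the rank-normalised split-chain
$\widehat{R}$ and bulk effective sample size, implemented in-package
(`rhat_rank()`, `ess_bulk()`); a fit with $\widehat{R} > 1.01$ or ESS
$\le 1000$ on any parameter carries a warning and `converged = FALSE`
rather than failing silently.

### Numerical choices

All curve evaluations run in natural-log space with a two-term
log-sum-exp, so speeds are accurate from $10^{-12}$ to beyond $10^{12}$ kg
(property tests probe these extremes; the empirical mass range alone spans
15 orders of magnitude). $d = 0$ is a valid parameter value that
degenerates the hump-shaped model into the saturating one -- the nesting
tests rely on it -- but `peak_mass()` then signals explicitly that no
interior maximum exists. The likelihood uses base-10 logs exactly as the
data model states, not natural logs.

## Model comparison

`psis_loo()` estimates each observation's expected log predictive density
under leave-one-out cross-validation by Pareto-smoothed importance
sampling: the largest importance weights are replaced by expected order
statistics of a generalised Pareto distribution fitted to them by the
empirical-Bayes profile method, and the tail-shape estimate $\hat k$
(regularised towards 0.5) diagnoses reliability. Observations with
$\hat k > 0.7$ are flagged; `psis_loo(fit, refit_high_k = TRUE)` replaces
them with exact refits. `LOOIC` $= -2\,\mathrm{ELPD}$, and
`compare_speed_models()` reports each model's LOOIC difference to the best
model with a standard error computed from the *paired* pointwise ELPD
differences, $\mathrm{SE} = \sqrt{n \,\mathrm{Var}(\Delta_i)}$ -- not from
the two models' independent SEs. A model is `"preferred"` only when every
rival trails by more than twice the SE of its difference. The
implementation is validated against brute-force exact leave-one-out
(refitting $n$ times, `exact_loo()`) on a 20-record instance, where the
two agree within a fraction of an ELPD unit provided the fit is well
identified; the suite also checks the converse, that an overparameterised
tiny-sample fit produces large $\hat k$ and triggers the refit fallback.
WAIC, Bayes factors and stacking are out of scope.

## Prediction intervals

`predict_curve()` summarises the posterior of the curve on a per-mode
log-spaced mass grid (200 points spanning the observed range extended one
order of magnitude each side, the extension flagged as extrapolation). Two
intervals are reported, because "uncertainty about the curve" and
"uncertainty about a new observation" are both of interest: the 90%
credible interval is the 5th/95th percentile of $f(M, \theta)$ over draws,
and the 90% prediction interval additionally carries the residual scatter,
computed analytically per draw -- each draw $s$ contributes its Gaussian
log10 quantiles $\mu_s \pm 1.645\,\sigma_s$ and the 5th/95th percentile is
taken across draws. This is deterministic given the draws (no noise is
simulated) and encloses the credible interval by construction. It is a
mildly conservative approximation to the exact predictive mixture
quantile (it adds the posterior spread of $\mu$ and the residual quantile
linearly rather than in quadrature); with the posterior concentrated, as
it is at the 699-record scale, the excess coverage is on the order of one
percentage point, which the interval-calibration test bounds explicitly
(86--94% empirical coverage of held-out data at the nominal 90%).

## The synthetic-data generator

`simulate_speed_data()` runs the data model forward and is the ground
truth for every end-to-end check: masses log-uniform per mode, speeds from
the chosen process model, Gaussian log10 noise. `default_sim_config()`
emulates the shape of the empirical compilations this model family is
fitted to: 699 records split evenly across modes (233/233/233), per-mode
log10-kg mass ranges of flying $[-10, 1.2]$, running $[-9, 4]$, swimming
$[-6, 5.15]$ -- a plausible partition whose union spans the published
$2\times10^{-10}$ to $1.4\times10^5$ kg extremes -- with the hump-shaped
model and `default_speed_params()` ($v_0 = 30.54/0.28/0.39$ m s$^{-1}$
kg$^{-c}$ for flying/running/swimming, $k_\lambda = 0.033$, $c = 0.27$,
$d = 0.24$) as truth. Residual scatter defaults to $\sigma = 0.3$ log10
units, a value chosen once to give scatter visually comparable to the
empirical compilations, which do not print their residual deviation.
Realms default from the mode (swimming aquatic, otherwise terrestrial) and
can be overridden per record.

What the generator deliberately does **not** emulate: the taxonomic
composition of real compilations, study-level clustering and shared
measurement error, measurement-method heterogeneity, or any
empirical-mixture mass distribution. Passing recovery and calibration
tests on this generator therefore demonstrates that the inference
machinery is correct under its own assumptions -- not that those
assumptions hold for any particular empirical dataset.

## Problem sizes used in validation

The package validates itself at two scales, chosen as a deliberate
trade-off between statistical resolution and desk-scale runtimes. Unit
tests use 60--300 records with short chains. The end-to-end acceptance
checks use the full emulation scale: five replicate 699-record datasets
fitted with the default protocol (each true parameter must fall inside
its 90% credible interval in at least 4 of 5 replicates, with
$\widehat{R} \le 1.01$ and ESS $> 1000$ throughout); a three-model
comparison on one such dataset (the hump-shaped truth must be preferred
with the power law trailing by more than twice the SE of its difference);
PSIS-LOO against 20 exact refits at $n = 20$; and 90% interval coverage
on 2,000 held-out records. The five-replicate design makes the recovery
check a small Monte Carlo experiment rather than a single lucky draw;
with seven parameters at nominal 90% coverage, occasional single-replicate
misses are expected and tolerated by the 4-of-5 rule.

## Reading external data

`read_speed_data()` accepts any CSV through a `column_map()` that renames
columns and converts units (g, tonnes, km/h, ...); every row is either
validated onto the canonical schema (`species`, `mass_kg`, `speed_m_s`,
`mode`, `realm`) or reported with its row number, offending value and
reason. `aggregate_species()` collapses individual-level records to one
per species by unweighted geometric means, the natural aggregation under
a log-scale Gaussian model. Converting body length to mass is out of
scope: the reader accepts only mass.

## Known limitations

* The three process models are deterministic in mass and mode; phylogeny,
  temperature, morphology and behaviour enter only through the residual
  scatter. Deviations of individual taxa from the curve are informative
  but not modelled.
* JAGS slice sampling needs the internal thinning described above to match
  the effective-sample-size contract; runtime scales accordingly
  (roughly two minutes for a 699-record hump-model fit on one CPU).
* PSIS-LOO is an approximation; at very small $n$ or with
  weakly-identified structures its $\hat k$ diagnostics must be heeded
  (the refit fallback exists for exactly that case).
* The per-realm model variants identify the aquatic/terrestrial contrast
  only from swimming versus non-swimming records unless realms are
  assigned explicitly per record.
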