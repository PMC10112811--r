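# allospeed

Allometric models of sustained animal travel speed: Bayesian fitting,
model comparison and prediction across flying, running and swimming
animals.

## The problem

Sustained (aerobic) travel speed is a core trait for predicting animal
movement — dispersal, migration, landscape connectivity — from easily
measured quantities. Within each locomotion mode, speed first rises with
body mass `M` as a power law (larger animals supply more metabolic power
and move more efficiently), but the largest animals slow down again: the
heat produced by working muscle must be dissipated, larger bodies have
more thermal inertia, and avoiding hyperthermia forces them to divert an
increasing share of the travel time budget to shedding heat. `allospeed`
implements the three process models that encode competing hypotheses about
this heat-dissipation time and the machinery to confront them with data:

| model | heat-dissipation time per metre | realised speed | shape |
|---|---|---|---|
| metabolic | none | `v = v0 M^c` | power law |
| constant heat-dissipation | `k0` | `v = (1/k0) M^c / (M^c + 1/(v0 k0))` | saturating |
| allometric heat-dissipation | `k_lambda M^d` | `v = (1/k_lambda) M^c / (M^(c+d) + 1/(v0 k_lambda))` | hump-shaped |

`v0` is a mode-specific locomotion rate constant; `c` is the
potential-speed exponent (mechanistically the sum of the aerobic-power
exponent, 0.80–0.97, and the locomotion-efficiency exponent, about −0.67,
hence expected in [0.13, 0.30], see `exponent_bounds()`); `d` is the
heat-dissipation exponent. The hump-shaped curve peaks at
`M* = (c K / d)^(1/(c+d))` with `K = 1/(v0 k_lambda)` (`peak_mass()`).

Fitting is Bayesian (Gaussian likelihood on log10 speed, weakly
informative priors, MCMC via JAGS with 3 chains × 3,000 retained draws),
model comparison uses PSIS leave-one-out cross-validation (ELPD / LOOIC
with paired standard errors of the differences), and prediction produces
posterior mean curves with 90% credible and prediction intervals,
flagged where they extrapolate beyond the observed mass range. A
synthetic-data generator with known ground truth makes the whole pipeline
testable end to end.

## Worked example

Simulate a 699-record dataset shaped like the empirical travel-speed
compilations (233 records per mode, masses spanning 2e-10 to 1.4e5 kg,
hump-shaped truth, scatter 0.3 log10 units), fit two rival models, and
compare them:

```r
library(allospeed)

dat <- simulate_speed_data(default_sim_config(seed = 1))
fit <- fit_speed_model(dat, mcmc = mcmc_config(seed = 1))   # hump-shaped
tidy(fit)
#> # A tibble: 7 × 7
#>   term        estimate std.error conf.low conf.high  rhat ess_bulk
#>   <chr>          <dbl>     <dbl>    <dbl>     <dbl> <dbl>    <dbl>
#> 1 c             0.273    0.00484   0.265     0.281  1.00     2606.
#> 2 d             0.218    0.0255    0.177     0.261  1.00     3970.
#> 3 k_lambda      0.0424   0.00823   0.0295    0.0565 1.00     3002.
#> 4 sigma         0.314    0.00845   0.300     0.328  1.000    8756.
#> 5 v0_flying    33.7      2.91     29.1      38.7    1.00     2819.
#> 6 v0_running    0.272    0.0172    0.244     0.301  1.00     4183.
#> 7 v0_swimming   0.363    0.0221    0.328     0.401  1.00     6015.

fit_met <- fit_speed_model(dat, speed_model("metabolic"),
                           mcmc = mcmc_config(seed = 2))
compare_speed_models(allometric_hd = fit, metabolic = fit_met)
#> # A tibble: 2 × 8
#>   model         description  elpd se_elpd looic delta_looic se_delta verdict
#>   <chr>         <chr>       <dbl>   <dbl> <dbl>       <dbl>    <dbl> <chr>
#> 1 allometric_hd hump-shaped -185.    19.1  369.         0        0   preferred
#> 2 metabolic     power law   -227.    18.6  454.        85.0     19.3 worse
```

Every true generator parameter sits inside its 90% credible interval
(`c = 0.27`, `d = 0.24`, `k_lambda = 0.033`, `v0 = 30.54/0.28/0.39`,
`sigma = 0.3`), all R-hat ≤ 1.01 with bulk ESS well above 1,000, and the
hump-shaped truth beats the power law by 85 LOOIC units — more than four
standard errors of the difference, so the verdict is `preferred`.

Prediction curves and the peak of the fitted hump:

```r
pc <- predict_curve(fit)          # per-mode grids, 90% CI + PI, extrapolation flags
autoplot(pc, data = dat)          # log-log curve plot
peak_mass(posterior_mean_params(fit), c("flying", "swimming"))
#> [1]    0.7617476 7675.1537658   # kg: flyers peak near 1 kg, swimmers in the 1e3-1e4 range
predict(fit, data.frame(mass_kg = 74000, mode = "swimming"))
#> # A tibble: 1 × 7
#>   mode     mass_kg  mean ci_low ci_high pi_low pi_high
#>   <chr>      <dbl> <dbl>  <dbl>   <dbl>  <dbl>   <dbl>
#> 1 swimming   74000  1.64   1.29    2.07  0.389    6.84
```

A 74-tonne swimmer (a fin whale, say) is predicted to cruise near 1.6 m/s
despite the metabolic potential for much more — the heat-dissipation
constraint in action.

Real data enter through `read_speed_data()` (any CSV via `column_map()`
with unit conversion and row-numbered validation) and
`aggregate_species()` (geometric-mean aggregation of individual records).

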