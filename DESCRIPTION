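Package: allospeed
Title: Allometric Models of Sustained Animal Travel Speed
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits and compares allometric models of sustained (aerobic)
    travel speed for flying, running and swimming animals. Implements three
    competing process models -- a power law driven by metabolic supply and
    locomotion efficiency, a saturating curve with a mass-independent
    heat-dissipation time, and a hump-shaped curve in which heat-dissipation
    time itself scales with body mass -- together with Bayesian MCMC fitting
    of all three under a Gaussian likelihood on log10 speed, approximate
    leave-one-out cross-validation (PSIS-LOO) for model comparison,
    posterior prediction curves with credible and prediction intervals, and
    a synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
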