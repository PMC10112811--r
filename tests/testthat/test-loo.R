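# PSIS-LOO and model comparison.

test_that("LOOIC is -2 x ELPD and self-comparison gives zero difference", {
  withr::with_seed(7, {
    ll <- matrix(rnorm(500 * 15, -1, 0.3), 500, 15)
  })
  l <- psis_loo(ll)
  expect_equal(l$looic, -2 * l$elpd, tolerance = 1e-12)
  expect_equal(l$se_looic, 2 * l$se_elpd, tolerance = 1e-12)
  expect_equal(nrow(l$pointwise), 15)

  fit <- small_ahd_fit()
  cmp <- compare_speed_models(a = fit, b = fit)
  expect_equal(cmp$delta_looic, c(0, 0))
  expect_equal(cmp$se_delta, c(0, 0))
  expect_true(all(cmp$verdict == "indistinguishable"))
})

test_that("degenerate all-identical draws are rejected", {
  ll <- matrix(-1.3, 200, 10)
  expect_error(psis_loo(ll), class = "allospeed_error_degenerate")
  expect_error(psis_loo(matrix(rnorm(50 * 4), 50, 4)),
               class = "allospeed_error_config") # too few draws
})

test_that("PSIS-LOO matches exact refit LOO within |delta ELPD| <= 1 at n = 20", {
  # a well-identified instance: single mode, power-law truth and fit, so the
  # importance weights are well behaved (all Pareto k-hat << 0.7)
  fit <- loo20_fit()
  psis <- psis_loo(fit)
  exact <- loo20_exact()
  expect_lt(abs(psis$elpd - exact$elpd), 1.0)
  expect_lt(max(psis$pointwise$pareto_k), 0.7)
})

test_that("exact refits replace observations PSIS flags as unreliable", {
  # an overparameterised fit at tiny n produces high Pareto k-hat; the
  # refit fallback replaces those pointwise terms
  d <- cached("loo20hd_data", small_dataset(n = 7, seed = 77)[1:20, ])
  fit <- cached("loo20hd_fit", suppressWarnings(fit_speed_model(
    d, mcmc = mcmc_config(chains = 2, warmup = 300, iter = 500, thin = 1, seed = 8)
  )))
  raw <- psis_loo(fit)
  expect_gt(sum(raw$pointwise$flagged), 0)
  ref <- psis_loo(fit, refit_high_k = TRUE)
  expect_false(any(ref$pointwise$flagged))
  expect_equal(ref$looic, -2 * ref$elpd, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(raw$elpd, ref$elpd)))
})

test_that("ELPD is invariant to consistent observation reordering", {
  fit <- small_ahd_fit()
  perm <- withr::with_seed(2, sample(ncol(fit$log_lik)))
  l1 <- psis_loo(fit$log_lik)
  l2 <- psis_loo(fit$log_lik[, perm])
  expect_equal(l1$elpd, l2$elpd, tolerance = 1e-12)
  expect_equal(l1$pointwise$elpd_i[perm], l2$pointwise$elpd_i, tolerance = 1e-12)
})

test_that("an observation identical under all models leaves the comparison unchanged", {
  fit <- small_ahd_fit()
  ll_a <- fit$log_lik[, 1:30]
  ll_b <- ll_a + matrix(rep(withr::with_seed(3, rnorm(30, 0, 0.05)),
                            each = nrow(ll_a)), nrow(ll_a), 30)
  shared <- matrix(-1, nrow(ll_a), 1) # same log-lik under both models
  d_elpd <- function(a, b) psis_loo(a)$elpd - psis_loo(b)$elpd
  base_delta <- d_elpd(ll_a, ll_b)
  aug_delta <- d_elpd(cbind(ll_a, shared), cbind(ll_b, shared))
  expect_equal(base_delta, aug_delta, tolerance = 1e-9)
})

test_that("the GPD tail-shape estimate recovers known Pareto tails", {
  withr::with_seed(12, {
    for (k_true in c(0.2, 0.5)) {
      u <- runif(3000)
      x <- (u^(-k_true) - 1) / k_true # GPD(sigma = 1, k = k_true) quantiles
      f <- allospeed:::gpd_fit(x)
      expect_lt(abs(f$k - k_true), 0.12)
    }
  })
})

test_that("power-law truth is not falsely beaten by the hump-shaped model", {
  tp <- speed_params(v0 = c(flying = 30.54, running = 0.28, swimming = 0.39),
                     c = 0.27, sigma = 0.3)
  d <- simulate_speed_data(sim_config(
    true_params = tp, n_per_mode = c(flying = 80, running = 80, swimming = 80),
    seed = 55
  ))
  fm <- suppressWarnings(fit_speed_model(d, speed_model("metabolic"),
                                         mcmc = small_mcmc(seed = 1)))
  fa <- suppressWarnings(fit_speed_model(d, mcmc = small_mcmc(seed = 2)))
  cmp <- compare_speed_models(metabolic = fm, allometric_hd = fa)
  met <- cmp[cmp$model == "metabolic", ]
  # the extra parameters must not buy a decisive advantage
  expect_false(met$verdict == "worse")
  expect_lte(met$delta_looic, 2 * max(met$se_delta, cmp$se_delta[1]) + 1e-9)
})

test_that("comparison refuses fits on different datasets", {
  fit <- small_ahd_fit()
  d2 <- small_dataset(n = 60, seed = 1001)
  fit2 <- cached("other_data_fit", suppressWarnings(fit_speed_model(
    d2, speed_model("metabolic"), mcmc = small_mcmc(seed = 9)
  )))
  expect_error(compare_speed_models(fit, fit2),
               class = "allospeed_error_config")
  expect_error(compare_speed_models(fit, "x"), class = "allospeed_error_config")
})
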