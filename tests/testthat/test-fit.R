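# MCMC fitting: recovery, invariances, misfit signatures, sensitivity.

test_that("near-noise-free data pin the posterior onto the true parameters", {
  truth <- ref_params(sigma = 1e-4)
  d <- simulate_speed_data(sim_config(
    true_params = truth,
    n_per_mode = c(flying = 100, running = 100, swimming = 100), seed = 6
  ))
  fit <- suppressWarnings(fit_speed_model(
    d, mcmc = mcmc_config(chains = 2, warmup = 500, iter = 800, thin = 1, seed = 7)
  ))
  est <- tidy(fit)
  want <- c(
    c = 0.27, d = 0.24, k_lambda = 0.033, v0_flying = 30.54,
    v0_running = 0.28, v0_swimming = 0.39
  )
  for (nm in names(want)) {
    got <- est$estimate[est$term == nm]
    expect_lt(abs(got - want[[nm]]) / want[[nm]], 0.01)
  }
})

test_that("the default protocol retains chains x iter draws with per-chain structure", {
  fit <- small_ahd_fit()
  expect_equal(nrow(fit$draws), 2 * 600)
  expect_equal(sort(unique(fit$draws$.chain)), 1:2)
  expect_setequal(
    fit$diagnostics$term,
    c("v0_flying", "v0_running", "v0_swimming", "k_lambda", "c", "d", "sigma")
  )
  expect_true(all(is.finite(fit$log_lik)))
  expect_equal(dim(fit$log_lik), c(1200, 180))
  # default config is the documented protocol
  mc <- mcmc_config()
  expect_equal(mc$chains * mc$iter, 9000)
  expect_equal(mc$warmup, 1500)
})

test_that("permuting record order leaves the posterior unchanged within MC error", {
  d <- small_dataset(n = 50, seed = 13)
  fit1 <- suppressWarnings(fit_speed_model(d, mcmc = small_mcmc(seed = 3)))
  perm <- withr::with_seed(1, sample(nrow(d)))
  fit2 <- suppressWarnings(fit_speed_model(d[perm, ], mcmc = small_mcmc(seed = 3)))
  t1 <- tidy(fit1)
  t2 <- tidy(fit2)
  mc_se <- t1$std.error / sqrt(pmin(t1$ess_bulk, t2$ess_bulk)) +
    t2$std.error / sqrt(pmin(t1$ess_bulk, t2$ess_bulk))
  expect_true(all(abs(t1$estimate - t2$estimate) < 5 * mc_se + 1e-8))
  # total likelihood itself is permutation invariant
  expect_equal(
    sum(pointwise_log_lik(d, ref_params())),
    sum(pointwise_log_lik(d[perm, ], ref_params()))
  )
})

test_that("fitting the power law to hump-shaped data leaves a systematic residual arc", {
  d <- cached("hump_for_misfit", simulate_speed_data(sim_config(
    n_per_mode = c(flying = 250), seed = 31
  )))
  fit <- cached("metab_misfit_fit", suppressWarnings(fit_speed_model(
    d, speed_model("metabolic"), mcmc = small_mcmc(seed = 4)
  )))
  est <- posterior_mean_params(fit)
  res <- log10(d$speed_m_s) - log10(realised_speed(d$mass_kg, d$mode, est,
                                                   spec = speed_model("metabolic")))
  lm10 <- log10(d$mass_kg)
  qs <- quantile(lm10, c(1 / 3, 2 / 3))
  mid <- res[lm10 > qs[1] & lm10 <= qs[2]]
  extreme <- res[lm10 <= qs[1] | lm10 > qs[2]]
  expect_gt(mean(mid), 0)
  expect_lt(mean(extreme), 0)
})

test_that("posterior is insensitive to a ten-fold broadening of the priors", {
  d <- small_dataset(n = 80, seed = 19)
  fit1 <- cached("sens_default", suppressWarnings(
    fit_speed_model(d, mcmc = small_mcmc(seed = 5))
  ))
  broad <- prior_config(c_scale = 10, d_scale = 10, v0_rate = 0.001,
                        k_rate = 0.1, sigma_scale = 25)
  fit2 <- suppressWarnings(fit_speed_model(d, priors = broad,
                                           mcmc = small_mcmc(seed = 5)))
  t1 <- tidy(fit1)
  t2 <- tidy(fit2)
  expect_true(all(
    abs(t2$estimate - t1$estimate) < 0.15 * abs(t1$estimate) + 3 * t1$std.error
  ))
})

test_that("simulation-based calibration ranks are uniform (reduced replicates)", {
  # draw truth from (moderated) priors, simulate, fit, rank the truth among
  # posterior draws; ranks should be uniform on [0, 1]
  # truths drawn from the same (moderate) priors the fit uses, so the rank
  # of the truth among posterior draws is uniform when fit and generator agree
  pri <- prior_config(c_scale = 0.3, d_scale = 0.3, v0_shape = 2, v0_rate = 2,
                      k_shape = 2, k_rate = 2, sigma_scale = 0.3)
  n_rep <- 12
  ranks <- withr::with_seed(55, {
    vapply(seq_len(n_rep), function(r) {
      truth <- speed_params(
        v0 = c(running = rgamma(1, 2, 2)),
        c = abs(rnorm(1, 0, 0.3)),
        d = abs(rnorm(1, 0, 0.3)),
        k_lambda = rgamma(1, 2, 2),
        sigma = abs(rcauchy(1, 0, 0.3))
      )
      d <- simulate_speed_data(sim_config(
        true_params = truth, n_per_mode = c(running = 60),
        mass_range_log10 = list(running = c(-3, 4)),
        seed = 1000 + r
      ))
      fit <- suppressWarnings(fit_speed_model(
        d, priors = pri,
        mcmc = mcmc_config(chains = 1, warmup = 300, iter = 400, thin = 2,
                           seed = 2000 + r)
      ))
      mean(fit$draws$c < truth$c)
    }, numeric(1))
  })
  expect_gt(suppressWarnings(stats::ks.test(ranks, "punif")$p.value), 0.01)
})

test_that("fit-time configuration errors are informative", {
  d <- small_dataset(n = 10, seed = 1)
  expect_error(
    fit_speed_model(d[d$mode == "flying", ][1, ], mcmc = small_mcmc()),
    class = "allospeed_error_config"
  )
  expect_error(fit_speed_model(d, spec = "metabolic"),
               class = "allospeed_error_config")
  bad <- d
  bad$mass_kg[3] <- -1
  expect_error(fit_speed_model(bad), class = "allospeed_error_validation")
})

test_that("tidy, glance, draws export and coda conversion are coherent", {
  fit <- small_ahd_fit()
  td <- tidy(fit)
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$nobs, 180)
  expect_equal(gl$n_draws, 1200)
  dr <- posterior_draws(fit)
  expect_equal(nrow(dr), 1200)
  ml <- coda::as.mcmc.list(fit)
  expect_s3_class(ml, "mcmc.list")
  expect_equal(coda::nchain(ml), 2)
  # posterior-mean parameter set plugs back into the curve functions
  pm <- posterior_mean_params(fit)
  expect_s3_class(pm, "speed_params")
  expect_true(is.finite(realised_speed(1, "flying", pm)))
})
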