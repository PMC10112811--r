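# Shared fixtures. Small fits are cached per test run so several test files
# can reuse them without refitting.

ref_params <- function(sigma = 0.3) default_speed_params(sigma = sigma)

# short MCMC protocol for unit tests (not the analysis default)
small_mcmc <- function(seed = 1, chains = 2, warmup = 300, iter = 600, thin = 1) {
  mcmc_config(chains = chains, warmup = warmup, iter = iter, thin = thin,
              seed = seed)
}

small_dataset <- function(n = 60, seed = 42, sigma = 0.3) {
  simulate_speed_data(sim_config(
    true_params = ref_params(sigma = sigma),
    n_per_mode = c(flying = n, running = n, swimming = n),
    seed = seed
  ))
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# one small hump-shaped fit shared across test files
small_ahd_fit <- function() {
  cached("small_ahd_fit", suppressWarnings(fit_speed_model(
    small_dataset(), mcmc = small_mcmc(seed = 11)
  )))
}

# n = 20 single-mode power-law instance where importance sampling is well
# behaved; shared between the LOO unit tests and the acceptance suite
loo20_fit <- function() {
  d <- cached("loo20_data", simulate_speed_data(sim_config(
    true_params = speed_params(v0 = c(running = 0.28), c = 0.27, sigma = 0.3),
    n_per_mode = c(running = 20), mass_range_log10 = list(running = c(-6, 3)),
    seed = 77
  )))
  cached("loo20_fit", suppressWarnings(fit_speed_model(
    d, speed_model("metabolic"),
    mcmc = mcmc_config(chains = 3, warmup = 400, iter = 700, thin = 1, seed = 8)
  )))
}

loo20_exact <- function() {
  cached("loo20_exact", exact_loo(loo20_fit()))
}

# random valid hump-shaped parameter sets for property-style tests
random_ahd_params <- function() {
  speed_params(
    v0 = c(flying = 10^runif(1, -1, 2), running = 10^runif(1, -1, 1),
           swimming = 10^runif(1, -1, 1)),
    c = runif(1, 0.05, 0.6),
    d = runif(1, 0.05, 0.6),
    k_lambda = 10^runif(1, -3, 0),
    sigma = runif(1, 0.1, 0.5)
  )
}
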