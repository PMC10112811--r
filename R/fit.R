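#' Pointwise Gaussian log-likelihood of speed records
#'
#' The data model is `log10(v_i) ~ Normal(log10 f(M_i, theta), sigma)` with
#' `f` the process-model curve. This returns the log-density contribution of
#' each record under one parameter set; their sum is the total data
#' log-likelihood.
#'
#' @param data Data frame of speed records (`mass_kg`, `speed_m_s`, `mode`,
#'   optionally `realm`).
#' @param params A [speed_params()] object.
#' @param spec A [speed_model()]; inferred from `params` when `NULL`.
#' @return Numeric vector, one log-density per record.
#' @export
pointwise_log_lik <- function(data, params, spec = NULL) {
  data <- as_speed_records(data, require_species = FALSE)
  spec <- spec %||% infer_spec(params)
  validate_params_for_spec(params, spec)
  mu <- log_realised_speed(
    log(data$mass_kg), data$mode, data$realm, params, spec
  ) / LN10
  dnorm(log10(data$speed_m_s), mean = mu, sd = params$sigma, log = TRUE)
}

# draws x observations log-likelihood matrix, vectorised over draws
loglik_from_draws <- function(draws, data, spec, modes, realms) {
  dm <- as.matrix(draws[setdiff(names(draws), c(".chain", ".iteration"))])
  y <- log10(data$speed_m_s)
  lM <- log(data$mass_kg)
  k_base <- if (spec$kind == "constant_hd") "k0" else "k_lambda"
  v0col <- paste0("v0_", data$mode)
  ccol <- if (spec$c_pooling == "by_mode") paste0("c_", data$mode) else rep("c", nrow(data))
  kcol <- if (spec$kind == "metabolic") {
    NULL
  } else if (spec$k_pooling == "by_realm") {
    paste0(k_base, "_", data$realm)
  } else {
    rep(k_base, nrow(data))
  }
  sig <- dm[, "sigma"]
  ll <- matrix(NA_real_, nrow(dm), nrow(data))
  for (i in seq_len(nrow(data))) {
    lv0 <- log(dm[, v0col[i]])
    cc <- dm[, ccol[i]]
    if (spec$kind == "metabolic") {
      mu <- (lv0 + cc * lM[i]) / LN10
    } else {
      lk <- log(dm[, kcol[i]])
      ex <- if (spec$kind == "allometric_hd") cc + dm[, "d"] else cc
      mu <- (cc * lM[i] - log_sum_exp2(ex * lM[i], -(lv0 + lk)) - lk) / LN10
    }
    ll[, i] <- dnorm(y[i], mean = mu, sd = sig, log = TRUE)
  }
  ll
}

#' Fit an allometric travel-speed model by MCMC
#'
#' Fits the chosen process model to species-level speed records under the
#' Gaussian log10-speed likelihood, with half-normal priors on the
#' exponents, gamma priors on the positive normalisation constants and a
#' half-Cauchy prior on `sigma`. Sampling uses JAGS; the locomotion rate
#' constant `v0` is always estimated independently for each mode present in
#' the data (no pooling), while `c` and the heat-dissipation constant follow
#' the pooling structure of `spec`. Initial values are drawn from the
#' priors, jittered per chain, and fixed by the seed.
#'
#' Convergence is assessed with rank-normalised split-chain R-hat and bulk
#' effective sample size for every free parameter; R-hat above 1.01 or ESS
#' at or below 1,000 raises a warning and marks the fit as not converged
#' (the fit is still returned for inspection).
#'
#' @param data Data frame of records (`mass_kg`, `speed_m_s`, `mode`,
#'   optional `realm` and `species`). Every fitted mode needs >= 2 records.
#' @param spec A [speed_model()].
#' @param priors A [prior_config()].
#' @param mcmc An [mcmc_config()].
#' @param quiet Suppress JAGS progress output.
#' @return A `speed_fit` object: posterior draws (tibble with `.chain` and
#'   `.iteration` columns), per-parameter diagnostics, the draws-by-records
#'   pointwise log-likelihood matrix, and the inputs needed to refit.
#' @examples
#' \donttest{
#' dat <- simulate_speed_data(default_sim_config(seed = 1))
#' fit <- fit_speed_model(dat, mcmc = mcmc_config(chains = 2, warmup = 300,
#'                                                iter = 500, seed = 1))
#' tidy(fit)
#' }
#' @export
fit_speed_model <- function(data, spec = speed_model(),
                            priors = prior_config(),
                            mcmc = mcmc_config(),
                            quiet = TRUE) {
  if (!inherits(spec, "speed_model_spec")) abort_config("`spec` must be a `speed_model_spec`.")
  if (!inherits(priors, "prior_config")) abort_config("`priors` must be a `prior_config`.")
  if (!inherits(mcmc, "mcmc_config")) abort_config("`mcmc` must be an `mcmc_config`.")
  data <- as_speed_records(data, require_species = FALSE)
  modes <- intersect(speed_modes(), unique(data$mode))
  n_mode <- table(factor(data$mode, levels = modes))
  if (any(n_mode < 2)) {
    abort_config(sprintf(
      "Each fitted mode needs >= 2 records; too few for: %s.",
      paste(names(n_mode)[n_mode < 2], collapse = ", ")
    ))
  }
  realms <- intersect(speed_realms(), unique(data$realm))
  if (spec$kind != "metabolic" && spec$k_pooling == "by_realm" &&
      length(realms) < 1) {
    abort_config("Per-realm k requested but no realm information present.")
  }

  seed <- mcmc$seed %||% sample.int(.Machine$integer.max, 1L)
  withr::local_seed(seed)
  rng_seeds <- sample.int(1e6, mcmc$chains)
  inits <- lapply(seq_len(mcmc$chains), function(ch) {
    jags_inits(spec, priors, modes, realms, rng_seeds[ch])
  })

  # pre-flight: the likelihood must be finite at every chain's start
  for (ch in seq_along(inits)) {
    p0 <- inits_to_params(inits[[ch]], spec, modes, realms)
    ll0 <- pointwise_log_lik(data, p0, spec)
    if (!all(is.finite(ll0))) {
      abort_config(paste0(
        "Non-finite likelihood at initialisation of chain ", ch,
        "; offending parameter values:\n",
        paste(utils::capture.output(print(p0)), collapse = "\n")
      ))
    }
  }

  model_str <- jags_model_string(spec)
  jdat <- jags_data(data, spec, priors, modes, realms)
  monitors <- c("v0", "c", if (spec$kind != "metabolic") "k",
                if (spec$kind == "allometric_hd") "d", "sigma")
  jm <- rjags::jags.model(
    textConnection(model_str), data = jdat, inits = inits,
    n.chains = mcmc$chains, n.adapt = mcmc$warmup, quiet = quiet
  )
  samp <- rjags::coda.samples(
    jm, variable.names = monitors,
    n.iter = mcmc$iter * mcmc$thin, thin = mcmc$thin,
    progress.bar = if (quiet) "none" else "text"
  )

  nm <- jags_name_map(coda::varnames(samp), spec, modes, realms)
  draws <- dplyr::bind_rows(lapply(seq_along(samp), function(ch) {
    m <- as.matrix(samp[[ch]])
    colnames(m) <- nm
    tibble::as_tibble(m) |>
      dplyr::mutate(.chain = ch, .iteration = dplyr::row_number(), .before = 1)
  }))

  pars <- unname(nm)
  diagnostics <- purrr::map_dfr(pars, function(p) {
    m <- matrix(draws[[p]], nrow = mcmc$iter, ncol = mcmc$chains)
    tibble::tibble(
      term = p,
      rhat = rhat_rank(m),
      ess_bulk = ess_bulk(m)
    )
  })
  converged <- all(diagnostics$rhat <= 1.01, na.rm = TRUE) &&
    all(diagnostics$ess_bulk > 1000)

  log_lik <- loglik_from_draws(draws, data, spec, modes, realms)

  fit <- structure(
    list(
      draws = draws, diagnostics = diagnostics, log_lik = log_lik,
      spec = spec, priors = priors, mcmc = mcmc, data = data,
      modes = modes, realms = realms, seed = seed, converged = converged
    ),
    class = "speed_fit"
  )
  if (!converged) {
    warn(
      paste0(
        "MCMC convergence criteria not met (max R-hat = ",
        format(max(diagnostics$rhat), digits = 4), ", min bulk ESS = ",
        format(round(min(diagnostics$ess_bulk))),
        "); inspect diagnostics before using this fit."
      ),
      class = "allospeed_warning_convergence"
    )
  }
  fit
}

#' @export
print.speed_fit <- function(x, ...) {
  cat("<speed_fit> ", x$spec$kind, " (", model_label(x$spec), "), ",
      nrow(x$data), " records, ", nrow(x$draws), " draws (",
      x$mcmc$chains, " chains)\n", sep = "")
  print(tidy(x), n = Inf)
  if (!x$converged) cat("  ! convergence criteria not met\n")
  invisible(x)
}

#' Posterior draws as a tibble
#'
#' One row per retained draw, one column per parameter, plus `.chain` and
#' `.iteration`. Write with [readr::write_csv()] for a plain tabular export.
#'
#' @param fit A `speed_fit`.
#' @return A tibble.
#' @export
posterior_draws <- function(fit) {
  stopifnot(inherits(fit, "speed_fit"))
  fit$draws
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of a fitted speed model
#'
#' @param x A `speed_fit`.
#' @param conf_level Width of the central credible interval.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (posterior mean), `std.error`
#'   (posterior SD), `conf.low`, `conf.high`, `rhat`, `ess_bulk`.
#' @exportS3Method generics::tidy
tidy.speed_fit <- function(x, conf_level = 0.90, ...) {
  a <- (1 - conf_level) / 2
  pars <- x$diagnostics$term
  purrr::map_dfr(pars, function(p) {
    v <- x$draws[[p]]
    tibble::tibble(
      term = p,
      estimate = mean(v),
      std.error = sd(v),
      conf.low = unname(quantile(v, a)),
      conf.high = unname(quantile(v, 1 - a))
    )
  }) |>
    dplyr::left_join(x$diagnostics, by = "term")
}

#' One-row summary of a fitted speed model
#'
#' @param x A `speed_fit`.
#' @param ... Unused.
#' @return Tibble with record/draw counts, worst-case diagnostics, the
#'   posterior-mean residual SD and the convergence flag.
#' @exportS3Method generics::glance
glance.speed_fit <- function(x, ...) {
  tibble::tibble(
    model = x$spec$kind,
    nobs = nrow(x$data),
    n_draws = nrow(x$draws),
    n_chains = x$mcmc$chains,
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess_bulk = min(x$diagnostics$ess_bulk),
    sigma = mean(x$draws$sigma),
    converged = x$converged
  )
}

#' Posterior means as a parameter set
#'
#' Collapses the posterior to its mean and repackages it as a
#' [speed_params()] object, convenient for plugging into [realised_speed()]
#' or [peak_mass()].
#'
#' @param fit A `speed_fit`.
#' @return A [speed_params()] object.
#' @export
posterior_mean_params <- function(fit) {
  stopifnot(inherits(fit, "speed_fit"))
  est <- colMeans(fit$draws[fit$diagnostics$term])
  draws_row_to_params(est, fit$spec, fit$modes, fit$realms)
}

# assemble a speed_params from a named vector of parameter values
draws_row_to_params <- function(v, spec, modes, realms) {
  v0 <- setNames(v[paste0("v0_", modes)], modes)
  cc <- if (spec$c_pooling == "by_mode") {
    setNames(v[paste0("c_", modes)], modes)
  } else {
    unname(v["c"])
  }
  k_base <- if (spec$kind == "constant_hd") "k0" else "k_lambda"
  k <- if (spec$kind == "metabolic") {
    NULL
  } else if (spec$k_pooling == "by_realm") {
    setNames(v[paste0(k_base, "_", realms)], realms)
  } else {
    unname(v[k_base])
  }
  speed_params(
    v0 = v0, c = cc, sigma = unname(v["sigma"]),
    k0 = if (spec$kind == "constant_hd") k else NULL,
    k_lambda = if (spec$kind == "allometric_hd") k else NULL,
    d = if (spec$kind == "allometric_hd") unname(v["d"]) else NULL
  )
}

#' Export draws as a coda `mcmc.list`
#'
#' `mcmc.list` is the standard R container for per-chain MCMC output and
#' plugs into the coda diagnostics toolbox.
#'
#' @param x A `speed_fit`.
#' @param ... Unused.
#' @return A [coda::mcmc.list].
#' @importFrom coda as.mcmc.list
#' @exportS3Method coda::as.mcmc.list
as.mcmc.list.speed_fit <- function(x, ...) {
  pars <- x$diagnostics$term
  coda::mcmc.list(lapply(split(x$draws, x$draws$.chain), function(d) {
    coda::mcmc(as.matrix(d[pars]))
  }))
}
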