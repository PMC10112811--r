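# JAGS backend: model-string construction and init generation.
#
# The likelihood is Gaussian on log10 speed with the process-model mean
# evaluated in natural-log space (exp/log of linear predictors), which is
# stable over the full mass range the priors can reach. v0 is always
# indexed by the locomotion modes present in the data; c and k are scalar
# or indexed by mode/realm according to the spec's pooling structure.

jags_model_string <- function(spec) {
  cc <- if (spec$c_pooling == "by_mode") "c[mode[i]]" else "c"
  kk <- if (spec$k_pooling == "by_realm") "k[realm[i]]" else "k"
  mu <- switch(spec$kind,
    metabolic = sprintf(
      "mu[i] <- (log(v0[mode[i]]) + %s * lM[i]) / %.15f", cc, LN10
    ),
    constant_hd = sprintf(
      "mu[i] <- (%s * lM[i] - log(exp(%s * lM[i]) + 1 / (v0[mode[i]] * %s)) - log(%s)) / %.15f",
      cc, cc, kk, kk, LN10
    ),
    allometric_hd = sprintf(
      "mu[i] <- (%s * lM[i] - log(exp((%s + d) * lM[i]) + 1 / (v0[mode[i]] * %s)) - log(%s)) / %.15f",
      cc, cc, kk, kk, LN10
    )
  )
  c_prior <- if (spec$c_pooling == "by_mode") {
    "for (m in 1:n_mode) { c[m] ~ dnorm(0, c_prec) T(0,) }"
  } else {
    "c ~ dnorm(0, c_prec) T(0,)"
  }
  k_prior <- if (spec$kind == "metabolic") {
    ""
  } else if (spec$k_pooling == "by_realm") {
    "for (r in 1:n_realm) { k[r] ~ dgamma(k_shape, k_rate) }"
  } else {
    "k ~ dgamma(k_shape, k_rate)"
  }
  d_prior <- if (spec$kind == "allometric_hd") "d ~ dnorm(0, d_prec) T(0,)" else ""
  paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    "    y[i] ~ dnorm(mu[i], tau)\n",
    "    ", mu, "\n",
    "  }\n",
    "  for (m in 1:n_mode) { v0[m] ~ dgamma(v0_shape, v0_rate) }\n",
    "  ", c_prior, "\n",
    "  ", k_prior, "\n",
    "  ", d_prior, "\n",
    "  sigma ~ dt(0, sigma_prec, 1) T(0,)\n",
    "  tau <- pow(sigma, -2)\n",
    "}\n"
  )
}

jags_data <- function(data, spec, priors, modes, realms) {
  dat <- list(
    N = nrow(data),
    y = log10(data$speed_m_s),
    lM = log(data$mass_kg),
    mode = match(data$mode, modes),
    n_mode = length(modes),
    v0_shape = priors$v0_shape, v0_rate = priors$v0_rate,
    c_prec = 1 / priors$c_scale^2,
    sigma_prec = 1 / priors$sigma_scale^2
  )
  if (spec$kind != "metabolic") {
    dat$k_shape <- priors$k_shape
    dat$k_rate <- priors$k_rate
  }
  if (spec$kind != "metabolic" && spec$k_pooling == "by_realm") {
    dat$realm <- match(data$realm, realms)
    dat$n_realm <- length(realms)
  }
  if (spec$kind == "allometric_hd") dat$d_prec <- 1 / priors$d_scale^2
  dat
}

# Draw one chain's initial values from the priors (central 80% to avoid
# numerically absurd starting points in the far tails), jittered by the
# chain's own uniforms; consumes the active RNG stream.
jags_inits <- function(spec, priors, modes, realms, rng_seed) {
  q <- prior_quantiles(priors)
  u <- function(n = 1) runif(n, 0.1, 0.9)
  ini <- list(
    v0 = q$v0(u(length(modes))),
    c = if (spec$c_pooling == "by_mode") q$c(u(length(modes))) else q$c(u()),
    sigma = q$sigma(u()),
    .RNG.name = "base::Mersenne-Twister",
    .RNG.seed = rng_seed
  )
  if (spec$kind != "metabolic") {
    ini$k <- if (spec$k_pooling == "by_realm") q$k(u(length(realms))) else q$k(u())
  }
  if (spec$kind == "allometric_hd") ini$d <- q$d(u())
  ini
}

# convert one inits list into a speed_params object (for the pre-flight
# finite-likelihood check)
inits_to_params <- function(ini, spec, modes, realms) {
  v0 <- setNames(ini$v0, modes)
  cc <- if (spec$c_pooling == "by_mode") setNames(ini$c, modes) else ini$c
  k <- if (spec$kind == "metabolic") {
    NULL
  } else if (spec$k_pooling == "by_realm") {
    setNames(ini$k, realms)
  } else {
    ini$k
  }
  speed_params(
    v0 = v0, c = cc, sigma = ini$sigma,
    k0 = if (spec$kind == "constant_hd") k else NULL,
    k_lambda = if (spec$kind == "allometric_hd") k else NULL,
    d = if (spec$kind == "allometric_hd") max(ini$d, 0) else NULL
  )
}

# map JAGS column names ("v0[2]", "c", "k[1]") to tidy parameter names
jags_name_map <- function(cols, spec, modes, realms) {
  k_base <- if (spec$kind == "constant_hd") "k0" else "k_lambda"
  vapply(cols, function(cn) {
    if (grepl("^v0\\[", cn)) {
      paste0("v0_", modes[as.integer(gsub("\\D", "", cn))])
    } else if (cn == "v0") {
      paste0("v0_", modes[1])
    } else if (grepl("^c\\[", cn)) {
      paste0("c_", modes[as.integer(gsub("\\D", "", cn))])
    } else if (grepl("^k\\[", cn)) {
      paste0(k_base, "_", realms[as.integer(gsub("\\D", "", cn))])
    } else if (cn == "k") {
      k_base
    } else {
      cn
    }
  }, character(1))
}
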