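# Approximate leave-one-out cross-validation by Pareto-smoothed importance
# sampling (PSIS). For each observation the importance ratios 1/p(y_i|theta)
# are stabilised by fitting a generalised Pareto distribution to the largest
# weights (empirical-Bayes profile fit) and replacing them with its expected
# order statistics; the tail-shape estimate k-hat diagnoses reliability.

# profile-posterior GPD fit to exceedances x > 0 (sorted internally);
# returns shape k (regularised towards 0.5) and scale sigma
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior <- 3
  m <- 30 + floor(sqrt(n))
  quart <- x[max(floor(n / 4 + 0.5), 1)]
  theta <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / (prior * quart)
  # profile works with shape -xi; heavy tails have theta < 0
  k_of <- function(b) -mean(log1p(-b * x))
  l <- vapply(theta, function(b) {
    k <- k_of(b)
    n * (log(b / k) + k - 1)
  }, numeric(1))
  w <- exp(l - max(l))
  w <- w / sum(w)
  theta_hat <- sum(theta * w)
  xi <- -k_of(theta_hat) # tail index, positive for heavy tails
  sigma <- -xi / theta_hat
  xi_reg <- (n * xi + 5) / (n + 10) # weak prior pulling the estimate to 0.5
  list(k = xi_reg, sigma = sigma)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) {
    -sigma * log1p(-p)
  } else {
    sigma * expm1(-k * log1p(-p)) / k
  }
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# smooth one observation's log importance weights; returns normalised log
# weights and the Pareto k-hat
psis_smooth_one <- function(lw) {
  s <- length(lw)
  lw <- lw - max(lw)
  tail_len <- ceiling(min(0.2 * s, 3 * sqrt(s)))
  khat <- NA_real_
  if (tail_len >= 5) {
    ord <- order(lw)
    tail_ids <- ord[seq(s - tail_len + 1, s)]
    cutoff <- lw[ord[s - tail_len]]
    exc <- exp(lw[tail_ids]) - exp(cutoff)
    if (length(unique(exc)) >= 2 && max(exc) > 0) {
      f <- gpd_fit(exc[exc > 0])
      khat <- f$k
      if (is.finite(khat)) {
        q <- gpd_quantile(
          (seq_len(tail_len) - 0.5) / tail_len, f$k, f$sigma
        )
        lw[tail_ids[order(lw[tail_ids])]] <- log(q + exp(cutoff))
      }
    } else {
      khat <- 0
    }
  }
  lw <- pmin(lw, 0) # truncate at the raw maximum
  list(log_weights = lw - log_sum_exp(lw), khat = khat)
}

#' PSIS leave-one-out cross-validation
#'
#' Estimates each observation's expected log predictive density (ELPD) under
#' leave-one-out cross-validation from the posterior draws alone, using
#' Pareto-smoothed importance sampling. `LOOIC = -2 * ELPD` puts the result
#' on the deviance scale (lower is better). Observations whose Pareto k-hat
#' exceeds `k_threshold` are flagged as unreliable; with a `speed_fit` they
#' can be recomputed by exact refits via `refit_high_k = TRUE`.
#'
#' @param x A `speed_fit`, or a draws-by-observations log-likelihood matrix
#'   with at least 100 draws.
#' @param k_threshold Pareto k-hat above which an observation is flagged.
#' @param refit_high_k Refit the model without each flagged observation and
#'   replace its ELPD by the exact value (requires a `speed_fit`).
#' @param ... Unused.
#' @return A `speed_loo` object with `elpd`, `se_elpd`, `looic`, `se_looic`
#'   and a `pointwise` tibble (`elpd_i`, `pareto_k`, `flagged`).
#' @export
psis_loo <- function(x, k_threshold = 0.7, refit_high_k = FALSE, ...) {
  UseMethod("psis_loo")
}

#' @export
psis_loo.speed_fit <- function(x, k_threshold = 0.7, refit_high_k = FALSE, ...) {
  out <- psis_loo(x$log_lik, k_threshold = k_threshold)
  if (refit_high_k && any(out$pointwise$flagged)) {
    bad <- which(out$pointwise$flagged)
    ex <- exact_loo(x, obs = bad)
    out$pointwise$elpd_i[bad] <- ex$pointwise$elpd_i
    out$pointwise$pareto_k[bad] <- NA_real_
    out$pointwise$flagged[bad] <- FALSE
    out$elpd <- sum(out$pointwise$elpd_i)
    out$se_elpd <- sqrt(nrow(out$pointwise) * var(out$pointwise$elpd_i))
    out$looic <- -2 * out$elpd
    out$se_looic <- 2 * out$se_elpd
  }
  out
}

#' @export
psis_loo.matrix <- function(x, k_threshold = 0.7, refit_high_k = FALSE, ...) {
  if (refit_high_k) {
    abort_config("`refit_high_k` needs a `speed_fit`, not a bare matrix.")
  }
  if (nrow(x) < 100) {
    abort_config("PSIS-LOO needs at least 100 posterior draws.")
  }
  if (any(!is.finite(x))) {
    abort_config("Non-finite pointwise log-likelihoods.")
  }
  col_sd <- apply(x, 2, sd)
  if (all(col_sd == 0)) {
    abort(
      "All draws are identical: importance weights are degenerate and PSIS-LOO is undefined.",
      class = "allospeed_error_degenerate"
    )
  }
  n <- ncol(x)
  elpd_i <- numeric(n)
  khat <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth_one(-x[, i])
    elpd_i[i] <- log_sum_exp(sm$log_weights + x[, i])
    khat[i] <- sm$khat
  }
  structure(
    list(
      elpd = sum(elpd_i),
      se_elpd = sqrt(n * var(elpd_i)),
      looic = -2 * sum(elpd_i),
      se_looic = 2 * sqrt(n * var(elpd_i)),
      n_obs = n, n_draws = nrow(x),
      pointwise = tibble::tibble(
        obs = seq_len(n), elpd_i = elpd_i, pareto_k = khat,
        flagged = !is.na(khat) & khat > k_threshold
      )
    ),
    class = "speed_loo"
  )
}

#' @export
print.speed_loo <- function(x, ...) {
  cat("<speed_loo> ", x$n_obs, " observations, ", x$n_draws, " draws\n", sep = "")
  cat(sprintf("  elpd  = %8.1f (SE %.1f)\n", x$elpd, x$se_elpd))
  cat(sprintf("  looic = %8.1f (SE %.1f)\n", x$looic, x$se_looic))
  nf <- sum(x$pointwise$flagged)
  if (nf > 0) cat("  !", nf, "observation(s) with Pareto k-hat > threshold\n")
  invisible(x)
}

#' Exact leave-one-out cross-validation by refitting
#'
#' Refits the model once per held-out observation and evaluates the exact
#' log predictive density of the left-out record. Brute force and slow;
#' intended for small datasets, for validating [psis_loo()], and as the
#' fallback for observations PSIS flags as unreliable.
#'
#' @param fit A `speed_fit` (its data, spec, priors and MCMC settings are
#'   reused; refit seeds are derived from the fit's seed).
#' @param obs Integer indices of observations to refit; default all.
#' @return A list with `elpd` (summed over `obs`) and a `pointwise` tibble.
#' @export
exact_loo <- function(fit, obs = NULL) {
  stopifnot(inherits(fit, "speed_fit"))
  obs <- obs %||% seq_len(nrow(fit$data))
  elpd_i <- vapply(obs, function(i) {
    mc <- fit$mcmc
    mc$seed <- (fit$seed + i) %% .Machine$integer.max
    refit <- suppressWarnings(fit_speed_model(
      fit$data[-i, , drop = FALSE],
      spec = fit$spec, priors = fit$priors, mcmc = mc
    ))
    ll <- loglik_from_draws(
      refit$draws, fit$data[i, , drop = FALSE],
      fit$spec, refit$modes, refit$realms
    )
    log_sum_exp(ll[, 1]) - log(nrow(ll))
  }, numeric(1))
  list(
    elpd = sum(elpd_i),
    pointwise = tibble::tibble(obs = obs, elpd_i = elpd_i)
  )
}

#' Compare fitted speed models by PSIS-LOO
#'
#' Computes ELPD and LOOIC for each fitted model, the LOOIC difference of
#' every model to the best (lowest-LOOIC) one, and the standard error of
#' each difference from the paired pointwise ELPD differences,
#' `SE = sqrt(n * var(elpd_diff_i))`. The best model is `"preferred"` only
#' if every rival trails by more than two standard errors of its
#' difference; rivals within two standard errors are `"indistinguishable"`,
#' the rest `"worse"`. All fits must be to the identical dataset.
#'
#' @param ... `speed_fit` objects (optionally named), or a single (named)
#'   list of them.
#' @param k_threshold Passed to [psis_loo()].
#' @return A `speed_comparison` tibble: `model`, `description`, `elpd`,
#'   `se_elpd`, `looic`, `delta_looic`, `se_delta`, `verdict`, ordered best
#'   first. Write with [readr::write_csv()] for a tabular export.
#' @export
compare_speed_models <- function(..., k_threshold = 0.7) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) && !inherits(fits[[1]], "speed_fit")) {
    fits <- fits[[1]]
  }
  if (length(fits) < 1L || !all(vapply(fits, inherits, TRUE, "speed_fit"))) {
    abort_config("Supply `speed_fit` objects (or one list of them).")
  }
  nms <- names(fits)
  auto <- vapply(fits, function(f) f$spec$kind, character(1))
  if (is.null(nms)) nms <- auto else nms[nms == ""] <- auto[nms == ""]
  nms <- make.unique(nms)

  n_obs <- vapply(fits, function(f) nrow(f$data), integer(1))
  if (length(unique(n_obs)) != 1L) {
    abort_config("All models must be fitted to the identical dataset (observation counts differ).")
  }
  ref <- fits[[1]]$data
  same <- vapply(fits[-1], function(f) {
    isTRUE(all.equal(f$data$mass_kg, ref$mass_kg)) &&
      isTRUE(all.equal(f$data$speed_m_s, ref$speed_m_s)) &&
      identical(f$data$mode, ref$mode)
  }, logical(1))
  if (!all(same)) {
    abort_config("All models must be fitted to the identical dataset (records differ).")
  }

  loos <- lapply(fits, psis_loo, k_threshold = k_threshold)
  elpd <- vapply(loos, `[[`, numeric(1), "elpd")
  best <- which.max(elpd)
  n <- n_obs[1]
  tab <- purrr::map_dfr(seq_along(fits), function(j) {
    di <- loos[[best]]$pointwise$elpd_i - loos[[j]]$pointwise$elpd_i
    se_delta <- if (j == best) 0 else 2 * sqrt(n * var(di))
    tibble::tibble(
      model = nms[j],
      description = model_label(fits[[j]]$spec),
      elpd = unname(elpd[j]),
      se_elpd = unname(loos[[j]]$se_elpd),
      looic = unname(loos[[j]]$looic),
      delta_looic = unname(loos[[j]]$looic - loos[[best]]$looic),
      se_delta = unname(se_delta)
    )
  })
  rivals_clear <- tab$delta_looic[-best] > 2 * tab$se_delta[-best]
  tab$verdict <- ifelse(
    seq_len(nrow(tab)) == best,
    if (length(rivals_clear) && all(rivals_clear)) "preferred" else "indistinguishable",
    ifelse(tab$delta_looic > 2 * tab$se_delta, "worse", "indistinguishable")
  )
  tab <- tab[order(-tab$elpd), ]
  structure(tab, class = c("speed_comparison", class(tibble::tibble())),
            pointwise = lapply(loos, function(l) l$pointwise))
}
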