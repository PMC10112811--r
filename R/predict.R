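# Posterior prediction: expected curves, credible intervals (uncertainty of
# the curve) and prediction intervals (curve plus residual sigma).
#
# Intervals are central quantile intervals. The prediction interval is
# assembled analytically per draw -- each draw contributes its Gaussian
# log10-quantiles mu_s + z * sigma_s -- and the draw-level quantile is then
# taken, so results are deterministic given the draws and the PI encloses
# the CI by construction (z < 0 lowers every draw's lower bound, z > 0
# raises every upper bound).

# draws-by-points matrix of log10 mean speeds
log10_mu_matrix <- function(fit, mass, mode, realm) {
  dm <- fit$draws
  lM <- log(mass)
  s <- nrow(dm)
  k_base <- if (fit$spec$kind == "constant_hd") "k0" else "k_lambda"
  mu <- matrix(NA_real_, s, length(mass))
  for (i in seq_along(mass)) {
    lv0 <- log(dm[[paste0("v0_", mode[i])]])
    cc <- if (fit$spec$c_pooling == "by_mode") dm[[paste0("c_", mode[i])]] else dm[["c"]]
    if (fit$spec$kind == "metabolic") {
      mu[, i] <- (lv0 + cc * lM[i]) / LN10
    } else {
      kname <- if (fit$spec$k_pooling == "by_realm") paste0(k_base, "_", realm[i]) else k_base
      lk <- log(dm[[kname]])
      ex <- if (fit$spec$kind == "allometric_hd") cc + dm[["d"]] else cc
      mu[, i] <- (cc * lM[i] - log_sum_exp2(ex * lM[i], -(lv0 + lk)) - lk) / LN10
    }
  }
  mu
}

col_quantile <- function(m, p) {
  apply(m, 2, quantile, probs = p, names = FALSE)
}

summarise_prediction <- function(fit, mass, mode, realm, level) {
  a <- (1 - level) / 2
  z <- qnorm(c(a, 1 - a))
  mu <- log10_mu_matrix(fit, mass, mode, realm)
  sig <- fit$draws$sigma
  tibble::tibble(
    mode = mode,
    mass_kg = mass,
    mean = colMeans(10^mu),
    ci_low = 10^col_quantile(mu, a),
    ci_high = 10^col_quantile(mu, 1 - a),
    pi_low = 10^col_quantile(mu + z[1] * sig, a),
    pi_high = 10^col_quantile(mu + z[2] * sig, 1 - a)
  )
}

#' Posterior prediction curves over a mass grid
#'
#' For each requested locomotion mode, evaluates the posterior of the
#' realised-speed curve on a log-spaced body-mass grid and summarises it as
#' the posterior mean speed, a central credible interval for the expected
#' curve, and a central prediction interval for a new observation (adding
#' the residual scatter `sigma` on the log10 scale). Grid points outside
#' the observed mass range of that mode are marked `in_range = FALSE`
#' (extrapolation).
#'
#' @param fit A `speed_fit`.
#' @param modes Locomotion modes to predict for; default all fitted modes.
#' @param mass_grid Optional numeric vector of masses (kg) used for every
#'   mode; default a per-mode grid of `n_grid` log-spaced points spanning
#'   the observed range extended by `extend` orders of magnitude each side.
#' @param n_grid Grid points per mode.
#' @param extend Orders of magnitude to extend beyond the observed range.
#' @param level Interval probability (default 90%).
#' @param data Records defining the observed mass range; defaults to the
#'   fitting data.
#' @return A `speed_curves` tibble: `mode`, `mass_kg`, `mean`, `ci_low`,
#'   `ci_high`, `pi_low`, `pi_high`, `in_range`.
#' @export
predict_curve <- function(fit, modes = NULL, mass_grid = NULL, n_grid = 200,
                          extend = 1, level = 0.90, data = NULL) {
  stopifnot(inherits(fit, "speed_fit"))
  modes <- modes %||% fit$modes
  bad <- setdiff(modes, fit$modes)
  if (length(bad)) {
    abort_config(paste0(
      "No fitted v0 for mode(s): ", paste(bad, collapse = ", "), "."
    ))
  }
  data <- data %||% fit$data
  out <- purrr::map(modes, function(m) {
    obs_range <- range(data$mass_kg[data$mode == m])
    grid <- mass_grid %||% 10^seq(
      log10(obs_range[1]) - extend, log10(obs_range[2]) + extend,
      length.out = n_grid
    )
    grid <- sort(grid)
    res <- summarise_prediction(
      fit, grid, rep(m, length(grid)), default_realm(rep(m, length(grid))),
      level
    )
    res$in_range <- grid >= obs_range[1] & grid <= obs_range[2]
    res
  })
  structure(dplyr::bind_rows(out),
            class = c("speed_curves", class(tibble::tibble())))
}

#' Posterior predictions at specific masses
#'
#' Like [predict_curve()] but for arbitrary (mass, mode) combinations given
#' in `newdata`, e.g. the expected sustained speed of a 74,000 kg swimmer.
#'
#' @param object A `speed_fit`.
#' @param newdata Data frame with `mass_kg` and `mode` (optional `realm`).
#' @param level Interval probability.
#' @param ... Unused.
#' @return A tibble with posterior mean and interval columns per row of
#'   `newdata`.
#' @export
predict.speed_fit <- function(object, newdata, level = 0.90, ...) {
  if (missing(newdata)) newdata <- object$data
  if (!all(c("mass_kg", "mode") %in% names(newdata))) {
    abort_config("`newdata` needs columns `mass_kg` and `mode`.")
  }
  bad <- setdiff(unique(newdata$mode), object$modes)
  if (length(bad)) {
    abort_config(paste0("No fitted v0 for mode(s): ", paste(bad, collapse = ", "), "."))
  }
  realm <- if ("realm" %in% names(newdata)) newdata$realm else default_realm(newdata$mode)
  summarise_prediction(object, newdata$mass_kg, newdata$mode, realm, level)
}

#' Empirical coverage of the prediction interval
#'
#' Fraction of records whose observed speed falls inside the central
#' prediction interval. On data simulated from the fitted model the 90%
#' interval should cover about 90% of held-out records.
#'
#' @param fit A `speed_fit`.
#' @param newdata Held-out records (`mass_kg`, `speed_m_s`, `mode`).
#' @param level Interval probability.
#' @return A single coverage proportion.
#' @export
pi_coverage <- function(fit, newdata, level = 0.90) {
  pred <- predict.speed_fit(fit, newdata, level = level)
  mean(newdata$speed_m_s >= pred$pi_low & newdata$speed_m_s <= pred$pi_high)
}
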