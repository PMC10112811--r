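#' Specify an allometric travel-speed model
#'
#' Three process models describe how sustained travel speed `v` (m/s) scales
#' with body mass `M` (kg). All three share the same potential travel speed
#' `v0 * M^c` set by metabolic power supply and locomotion efficiency; they
#' differ in how much of the travel time budget is diverted to dissipating
#' metabolic heat:
#'
#' * `"metabolic"` -- no heat-dissipation time: `v = v0 * M^c`, a power law.
#' * `"constant_hd"` -- a mass-independent heat-dissipation time per unit
#'   distance (`k0`, s/m): `v = (1/k0) * M^c / (M^c + 1/(v0*k0))`, a
#'   saturating curve approaching `1/k0`.
#' * `"allometric_hd"` -- heat-dissipation time per unit distance grows with
#'   mass as `k_lambda * M^d`:
#'   `v = (1/k_lambda) * M^c / (M^(c+d) + 1/(v0*k_lambda))`, a hump-shaped
#'   curve peaking at intermediate mass.
#'
#' The locomotion rate constant `v0` is always estimated independently per
#' locomotion mode (no pooling). Optionally the exponent `c` can vary by
#' mode and the heat-dissipation constant by realm (aquatic vs terrestrial).
#' The default -- hump-shaped model, pooled `c`, pooled `k` -- is the most
#' parsimonious structure supported by empirical travel-speed compilations.
#'
#' @param kind One of `"allometric_hd"`, `"constant_hd"`, `"metabolic"`.
#' @param c_pooling `"pooled"` (one exponent `c`) or `"by_mode"`.
#' @param k_pooling `"pooled"` (one heat-dissipation constant) or
#'   `"by_realm"`. Ignored for the metabolic model.
#' @return A `speed_model_spec` object.
#' @examples
#' speed_model()
#' speed_model("metabolic")
#' @export
speed_model <- function(kind = c("allometric_hd", "constant_hd", "metabolic"),
                        c_pooling = c("pooled", "by_mode"),
                        k_pooling = c("pooled", "by_realm")) {
  kind <- match.arg(kind)
  c_pooling <- match.arg(c_pooling)
  k_pooling <- match.arg(k_pooling)
  if (kind == "metabolic") k_pooling <- "pooled" # irrelevant, normalised
  structure(
    list(kind = kind, c_pooling = c_pooling, k_pooling = k_pooling),
    class = "speed_model_spec"
  )
}

#' @export
print.speed_model_spec <- function(x, ...) {
  lab <- model_label(x)
  cat("<speed_model_spec> ", x$kind, " (", lab, ")\n", sep = "")
  cat("  c: ", x$c_pooling, if (x$kind != "metabolic")
    paste0(";  k: ", x$k_pooling), "\n", sep = "")
  invisible(x)
}

model_label <- function(spec) {
  switch(spec$kind,
    metabolic = "power law",
    constant_hd = "saturating",
    allometric_hd = "hump-shaped"
  )
}

#' Parameter set for an allometric travel-speed model
#'
#' Bundles one full parameter vector: the per-mode locomotion rate constants
#' `v0` (m s^-1 kg^-c), the potential-speed exponent `c`, the residual
#' standard deviation `sigma` (log10 m/s units), and -- for the
#' heat-dissipation models -- exactly one of the heat-dissipation time
#' constants `k0` (s/m, constant model) or `k_lambda` (s m^-1 kg^-d,
#' allometric model) plus, for the latter, the heat-dissipation exponent `d`.
#'
#' @param v0 Named positive numeric vector keyed by locomotion mode, e.g.
#'   `c(flying = 30, running = 0.3, swimming = 0.4)`.
#' @param c Positive exponent; a scalar, or a named vector by mode.
#' @param sigma Positive residual standard deviation on log10 speed.
#' @param k0 Heat-dissipation time constant of the saturating model; scalar
#'   or named by realm. Mutually exclusive with `k_lambda`.
#' @param k_lambda Heat-dissipation time constant of the hump-shaped model;
#'   scalar or named by realm.
#' @param d Non-negative heat-dissipation exponent (hump-shaped model).
#'   `d = 0` is allowed and degenerates to the saturating model.
#' @return A `speed_params` object.
#' @examples
#' default_speed_params()
#' @export
speed_params <- function(v0, c, sigma, k0 = NULL, k_lambda = NULL, d = NULL) {
  if (is.null(names(v0)) || !all(names(v0) %in% speed_modes())) {
    abort_config(
      "`v0` must be a named vector keyed by locomotion mode (flying/running/swimming)."
    )
  }
  if (!all(is.finite(v0)) || any(v0 <= 0)) {
    abort_config("All `v0` entries must be positive and finite.")
  }
  if (!is.null(names(c)) && !all(names(c) %in% speed_modes())) {
    abort_config("Per-mode `c` must be named by locomotion mode.")
  }
  if (!all(is.finite(c)) || any(c <= 0)) {
    abort_config("`c` must be positive and finite.")
  }
  check_positive_scalar(sigma, "sigma")
  if (!is.null(k0) && !is.null(k_lambda)) {
    abort_config("Supply at most one of `k0` and `k_lambda`, not both.")
  }
  for (nm in c("k0", "k_lambda")) {
    k <- get(nm)
    if (!is.null(k)) {
      if (!is.null(names(k)) && !all(names(k) %in% speed_realms())) {
        abort_config(sprintf("Per-realm `%s` must be named by realm.", nm))
      }
      if (!all(is.finite(k)) || any(k <= 0)) {
        abort_config(sprintf("`%s` must be positive and finite.", nm))
      }
    }
  }
  if (!is.null(d)) check_positive_scalar(d, "d", allow_zero = TRUE)
  structure(
    list(v0 = v0, c = c, sigma = sigma, k0 = k0, k_lambda = k_lambda, d = d),
    class = "speed_params"
  )
}

#' @export
print.speed_params <- function(x, ...) {
  cat("<speed_params>\n")
  cat("  v0    :", paste(sprintf("%s=%g", names(x$v0), x$v0), collapse = ", "), "\n")
  cat("  c     :", paste(sprintf(
    "%s%g", if (is.null(names(x$c))) "" else paste0(names(x$c), "="), x$c
  ), collapse = ", "), "\n")
  if (!is.null(x$k0)) {
    cat("  k0    :", paste(sprintf(
      "%s%g", if (is.null(names(x$k0))) "" else paste0(names(x$k0), "="), x$k0
    ), collapse = ", "), "\n")
  }
  if (!is.null(x$k_lambda)) {
    cat("  k_lambda:", paste(sprintf(
      "%s%g", if (is.null(names(x$k_lambda))) "" else paste0(names(x$k_lambda), "="),
      x$k_lambda
    ), collapse = ", "), "\n")
  }
  if (!is.null(x$d)) cat("  d     :", x$d, "\n")
  cat("  sigma :", x$sigma, "\n")
  invisible(x)
}

#' Reference parameter values for the hump-shaped model
#'
#' A parameter set representative of empirical fits of the hump-shaped
#' (allometric heat-dissipation) model to large cross-species travel-speed
#' compilations: flying animals have a roughly 100-fold larger locomotion
#' rate constant than runners or swimmers, potential speed scales with an
#' exponent near 0.27, and heat-dissipation time with an exponent near 0.24.
#' Used as the default ground truth of the synthetic-data generator.
#'
#' @param sigma Residual standard deviation on log10 speed (the generator's
#'   noise level; 0.3 gives scatter comparable to empirical compilations).
#' @return A [speed_params()] object.
#' @export
default_speed_params <- function(sigma = 0.3) {
  speed_params(
    v0 = c(flying = 30.54, running = 0.28, swimming = 0.39),
    c = 0.27, d = 0.24, k_lambda = 0.033, sigma = sigma
  )
}

# infer the model spec a parameter set belongs to (by which k is present)
infer_spec <- function(params) {
  if (!is.null(params$k_lambda)) {
    speed_model("allometric_hd",
      k_pooling = if (length(params$k_lambda) > 1) "by_realm" else "pooled",
      c_pooling = if (length(params$c) > 1) "by_mode" else "pooled"
    )
  } else if (!is.null(params$k0)) {
    speed_model("constant_hd",
      k_pooling = if (length(params$k0) > 1) "by_realm" else "pooled",
      c_pooling = if (length(params$c) > 1) "by_mode" else "pooled"
    )
  } else {
    speed_model("metabolic",
      c_pooling = if (length(params$c) > 1) "by_mode" else "pooled"
    )
  }
}

# check a parameter set is complete for a spec; returns normalised pieces
validate_params_for_spec <- function(params, spec) {
  if (!inherits(params, "speed_params")) {
    abort_config("`params` must be a `speed_params` object.")
  }
  k <- switch(spec$kind,
    metabolic = NULL,
    constant_hd = params$k0,
    allometric_hd = params$k_lambda
  )
  if (spec$kind != "metabolic" && is.null(k)) {
    abort_config(sprintf(
      "Model '%s' needs `%s`, which is absent from `params`.",
      spec$kind, if (spec$kind == "constant_hd") "k0" else "k_lambda"
    ))
  }
  if (spec$kind == "allometric_hd" && is.null(params$d)) {
    abort_config("Model 'allometric_hd' needs exponent `d`.")
  }
  invisible(k)
}

# resolve per-record parameter values (vectorised over records)
param_at <- function(x, key, what) {
  if (length(x) == 1L && is.null(names(x))) {
    rep_len(unname(x), length(key))
  } else {
    out <- unname(x[key])
    if (anyNA(out)) {
      abort_config(sprintf(
        "`%s` has no entry for: %s.", what,
        paste(unique(key[is.na(out)]), collapse = ", ")
      ))
    }
    out
  }
}

#' Realised travel speed under an allometric model
#'
#' Evaluates the closed-form realised travel speed of the chosen process
#' model at the given body masses. Computation is carried out in log space so
#' results remain accurate across masses spanning many orders of magnitude
#' (the empirical range alone covers 15).
#'
#' @param mass Positive body mass(es) in kg.
#' @param mode Locomotion mode(s), recycled against `mass`.
#' @param params A [speed_params()] object.
#' @param spec A [speed_model()] spec; if `NULL`, inferred from which
#'   heat-dissipation constant `params` carries.
#' @param realm Realm(s); only needed when the heat-dissipation constant is
#'   per-realm. Defaults to [default_realm()] of the mode.
#' @return Numeric vector of speeds in m/s.
#' @examples
#' realised_speed(74000, "swimming", default_speed_params())
#' @export
realised_speed <- function(mass, mode, params, spec = NULL, realm = NULL) {
  if (!is.numeric(mass) || any(!is.finite(mass)) || any(mass <= 0)) {
    abort_domain("`mass` must be positive and finite (kg).")
  }
  bad <- setdiff(unique(mode), speed_modes())
  if (length(bad)) {
    abort_validation(paste0("Unknown locomotion mode: ", paste(bad, collapse = ", ")))
  }
  spec <- spec %||% infer_spec(params)
  k <- validate_params_for_spec(params, spec)
  n <- max(length(mass), length(mode))
  mass <- rep_len(mass, n)
  mode <- rep_len(mode, n)
  realm <- rep_len(realm %||% default_realm(mode), n)
  exp(log_realised_speed(log(mass), mode, realm, params, spec))
}

# natural-log realised speed; the numerical core shared with the likelihood
log_realised_speed <- function(log_mass, mode, realm, params, spec) {
  v0 <- param_at(params$v0, mode, "v0")
  cc <- param_at(params$c, mode, "c")
  if (spec$kind == "metabolic") {
    return(log(v0) + cc * log_mass)
  }
  k <- if (spec$kind == "constant_hd") params$k0 else params$k_lambda
  kk <- param_at(k, realm, if (spec$kind == "constant_hd") "k0" else "k_lambda")
  ex <- if (spec$kind == "constant_hd") cc else cc + params$d
  # v = (1/k) * M^c / (M^ex + 1/(v0 k));  log K = -(log v0 + log k)
  logK <- -(log(v0) + log(kk))
  cc * log_mass - log_sum_exp2(ex * log_mass, logK) - log(kk)
}

#' Potential travel speed (no heat constraint)
#'
#' The speed permitted by metabolic power supply and locomotion efficiency
#' alone, `v0 * M^c` -- the common backbone of all three process models.
#'
#' @inheritParams realised_speed
#' @return Numeric vector of speeds in m/s.
#' @export
potential_speed <- function(mass, mode, params) {
  if (!is.numeric(mass) || any(!is.finite(mass)) || any(mass <= 0)) {
    abort_domain("`mass` must be positive and finite (kg).")
  }
  n <- max(length(mass), length(mode))
  mass <- rep_len(mass, n)
  mode <- rep_len(mode, n)
  v0 <- param_at(params$v0, mode, "v0")
  cc <- param_at(params$c, mode, "c")
  exp(log(v0) + cc * log(mass))
}

#' Body mass at which the hump-shaped speed curve peaks
#'
#' For the hump-shaped (allometric heat-dissipation) model the realised
#' speed `v = (1/k) * M^c / (M^(c+d) + K)` with `K = 1/(v0*k)` has a unique
#' interior maximum at `M* = (c*K/d)^(1/(c+d))`. Larger potential speeds
#' (larger `v0`) push the peak to smaller masses, which is why flying
#' animals saturate around 1 kg while runners and swimmers saturate in the
#' thousands of kg.
#'
#' @param params A [speed_params()] with `k_lambda` and `d > 0`.
#' @param mode Locomotion mode(s).
#' @param realm Realm(s) for per-realm `k_lambda`; defaults from mode.
#' @return Peak body mass(es) in kg.
#' @examples
#' peak_mass(default_speed_params(), "flying")
#' @export
peak_mass <- function(params, mode, realm = NULL) {
  if (is.null(params$k_lambda) || is.null(params$d)) {
    abort_config("`peak_mass()` needs hump-shaped parameters (`k_lambda` and `d`).")
  }
  if (params$d == 0) {
    abort(
      "d = 0: the curve is saturating and has no interior maximum.",
      class = c("allospeed_error_no_peak", "allospeed_error_domain")
    )
  }
  realm <- rep_len(realm %||% default_realm(mode), length(mode))
  v0 <- param_at(params$v0, mode, "v0")
  cc <- param_at(params$c, mode, "c")
  kk <- param_at(params$k_lambda, realm, "k_lambda")
  logK <- -(log(v0) + log(kk))
  exp((log(cc) + logK - log(params$d)) / (cc + params$d))
}

#' Theoretical bounds on the potential-speed exponent
#'
#' Potential travel speed scales as `M^(a+b)` where `a` is the exponent of
#' whole-organism aerobic metabolic power and `b` that of maximum locomotion
#' efficiency, so interval bounds on `a` translate additively into bounds on
#' `c = a + b`. With aerobic power scaling between 0.80 and 0.97 and
#' locomotion efficiency as about -0.67, the expected exponent lies between
#' 0.13 and 0.30.
#'
#' @param a_range Length-2 numeric interval for the metabolic power exponent.
#' @param b Locomotion-efficiency exponent (typically negative).
#' @return Named numeric `c(lower, upper)` bounding `c = a + b`.
#' @examples
#' exponent_bounds(c(0.80, 0.97), -0.67)
#' @export
exponent_bounds <- function(a_range, b) {
  if (!is.numeric(a_range) || length(a_range) != 2L || any(!is.finite(a_range))) {
    abort_config("`a_range` must be a finite numeric interval of length 2.")
  }
  check <- is.numeric(b) && length(b) == 1L && is.finite(b)
  if (!check) abort_config("`b` must be a single finite number.")
  r <- sort(a_range) + b
  c(lower = r[1], upper = r[2])
}

#' Theoretical exponent bounds as a bundle
#'
#' Collects the mechanistic exponent intervals: the metabolic power exponent
#' interval `a_range`, the locomotion-efficiency exponent `b`, the implied
#' potential-speed exponent interval `c_range = a_range + b`, and (if
#' supplied) an interval for the heat-dissipation exponent `d`.
#'
#' @inheritParams exponent_bounds
#' @param d_range Optional length-2 interval for `d`.
#' @return A `theory_bounds` list.
#' @export
theory_bounds <- function(a_range = c(0.80, 0.97), b = -0.67, d_range = NULL) {
  cr <- exponent_bounds(a_range, b)
  if (!is.null(d_range)) {
    if (!is.numeric(d_range) || length(d_range) != 2L) {
      abort_config("`d_range` must be a numeric interval of length 2.")
    }
    d_range <- sort(d_range)
  }
  structure(
    list(a_range = sort(a_range), b = b, c_range = cr, d_range = d_range),
    class = "theory_bounds"
  )
}

#' @export
print.theory_bounds <- function(x, ...) {
  cat("<theory_bounds>\n")
  cat(sprintf("  a in [%g, %g], b = %g\n", x$a_range[1], x$a_range[2], x$b))
  cat(sprintf("  c = a + b in [%g, %g]\n", x$c_range[1], x$c_range[2]))
  if (!is.null(x$d_range)) {
    cat(sprintf("  d in [%g, %g]\n", x$d_range[1], x$d_range[2]))
  }
  invisible(x)
}
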