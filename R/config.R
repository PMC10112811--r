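# YAML round-trip for analysis configuration: model spec, priors, MCMC
# protocol, simulation setup and column map, under top-level keys `model`,
# `priors`, `mcmc`, `simulation`, `column_map`. Only sections present in
# the file are returned.

params_to_list <- function(p) {
  out <- list(v0 = as.list(p$v0), c = if (is.null(names(p$c))) p$c else as.list(p$c),
              sigma = p$sigma)
  if (!is.null(p$k0)) out$k0 <- if (is.null(names(p$k0))) p$k0 else as.list(p$k0)
  if (!is.null(p$k_lambda)) {
    out$k_lambda <- if (is.null(names(p$k_lambda))) p$k_lambda else as.list(p$k_lambda)
  }
  if (!is.null(p$d)) out$d <- p$d
  out
}

list_to_params <- function(x) {
  unl <- function(v) if (is.list(v)) unlist(v) else v
  speed_params(
    v0 = unl(x$v0), c = unl(x$c), sigma = x$sigma,
    k0 = if (!is.null(x$k0)) unl(x$k0),
    k_lambda = if (!is.null(x$k_lambda)) unl(x$k_lambda),
    d = x$d
  )
}

#' Read an analysis configuration from YAML
#'
#' Reconstructs [speed_model()], [prior_config()], [mcmc_config()],
#' [sim_config()] and [column_map()] objects from the sections of a YAML
#' file; sections that are absent are omitted from the result.
#'
#' @param path Path to a YAML file.
#' @return A named list of configuration objects.
#' @seealso [write_analysis_config()]
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) abort_config(paste0("File not found: ", path))
  raw <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(raw$model)) {
    out$model <- speed_model(
      kind = raw$model$kind %||% "allometric_hd",
      c_pooling = raw$model$c_pooling %||% "pooled",
      k_pooling = raw$model$k_pooling %||% "pooled"
    )
  }
  if (!is.null(raw$priors)) out$priors <- do.call(prior_config, raw$priors)
  if (!is.null(raw$mcmc)) out$mcmc <- do.call(mcmc_config, raw$mcmc)
  if (!is.null(raw$simulation)) {
    s <- raw$simulation
    out$simulation <- sim_config(
      true_params = if (!is.null(s$true_params)) {
        list_to_params(s$true_params)
      } else {
        default_speed_params()
      },
      n_per_mode = unlist(s$n_per_mode %||%
        list(flying = 233, running = 233, swimming = 233)),
      mass_range_log10 = s$mass_range_log10 %||% list(
        flying = c(-10, 1.2), running = c(-9, 4), swimming = c(-6, 5.15)
      ),
      seed = s$seed
    )
  }
  if (!is.null(raw$column_map)) out$column_map <- do.call(column_map, raw$column_map)
  out
}

#' Write an analysis configuration to YAML
#'
#' @param config Named list with any of `model`, `priors`, `mcmc`,
#'   `simulation`, `column_map` (the objects produced by their
#'   constructors).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_analysis_config <- function(config, path) {
  out <- list()
  if (!is.null(config$model)) out$model <- unclass(config$model)
  if (!is.null(config$priors)) out$priors <- unclass(config$priors)
  if (!is.null(config$mcmc)) {
    m <- unclass(config$mcmc)
    out$mcmc <- m[!vapply(m, is.null, logical(1))]
  }
  if (!is.null(config$simulation)) {
    s <- config$simulation
    out$simulation <- list(
      true_params = params_to_list(s$true_params),
      n_per_mode = as.list(s$n_per_mode),
      mass_range_log10 = s$mass_range_log10
    )
    if (!is.null(s$seed)) out$simulation$seed <- s$seed
  }
  if (!is.null(config$column_map)) out$column_map <- unclass(config$column_map)
  yaml::write_yaml(out, path)
  invisible(path)
}
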