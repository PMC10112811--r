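#' @importFrom rlang abort warn %||% .data
#' @importFrom stats dnorm pnorm qnorm rnorm runif quantile var sd median
#'   setNames qgamma acf fft
NULL

LN10 <- log(10)

#' Locomotion modes and realms recognised by the package
#'
#' Every speed record is keyed by one of three locomotion modes; the realm
#' (the medium the animal dissipates heat into) is only needed for the
#' per-realm variants of the heat-dissipation models.
#'
#' @format Character vectors.
#' @name modes
NULL

#' @rdname modes
#' @export
speed_modes <- function() c("flying", "running", "swimming")

#' @rdname modes
#' @export
speed_realms <- function() c("aquatic", "terrestrial")

#' Default realm for a locomotion mode
#'
#' Swimming animals shed heat into water, flying and running animals into
#' air, so records without an explicit realm are assigned aquatic/terrestrial
#' accordingly.
#'
#' @param mode Character vector of locomotion modes.
#' @return Character vector of realms.
#' @export
default_realm <- function(mode) {
  ifelse(mode == "swimming", "aquatic", "terrestrial")
}

# log(exp(a) + exp(b)), elementwise, without overflow
log_sum_exp2 <- function(a, b) {
  m <- pmax(a, b)
  # when one side is -Inf the other dominates exactly
  out <- m + log1p(exp(-abs(a - b)))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

abort_domain <- function(msg, ...) {
  abort(msg, class = "allospeed_error_domain", ...)
}

abort_config <- function(msg, ...) {
  abort(msg, class = "allospeed_error_config", ...)
}

abort_validation <- function(msg, ...) {
  abort(msg, class = "allospeed_error_validation", ...)
}

check_positive_scalar <- function(x, name, allow_zero = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (if (allow_zero) x < 0 else x <= 0)) {
    abort_config(sprintf(
      "`%s` must be a single finite %s number, got %s.",
      name, if (allow_zero) "non-negative" else "positive",
      paste(format(x), collapse = ", ")
    ))
  }
  invisible(x)
}
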