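#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_ribbon geom_point
#'   geom_pointrange scale_x_log10 scale_y_log10 labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

mode_colours <- c(flying = "#2e7d32", running = "#c62828", swimming = "#1565c0")

#' Plot posterior prediction curves
#'
#' Log-log chart of realised travel speed against body mass: posterior mean
#' curve per locomotion mode (solid inside the observed mass range, dashed
#' where extrapolated) with interval ribbons. Flying is green, running red,
#' swimming blue.
#'
#' @param object A `speed_curves` tibble from [predict_curve()].
#' @param data Optional records to overlay as points.
#' @param interval `"ci"` (credible interval of the expected curve),
#'   `"pi"` (prediction interval) or `"both"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.speed_curves <- function(object, data = NULL,
                                  interval = c("both", "ci", "pi"), ...) {
  interval <- match.arg(interval)
  p <- ggplot(object, aes(x = .data$mass_kg, colour = .data$mode,
                          fill = .data$mode))
  if (interval %in% c("both", "pi")) {
    p <- p + geom_ribbon(aes(ymin = .data$pi_low, ymax = .data$pi_high),
                         alpha = 0.10, colour = NA)
  }
  if (interval %in% c("both", "ci")) {
    p <- p + geom_ribbon(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         alpha = 0.25, colour = NA)
  }
  if (!is.null(data)) {
    p <- p + geom_point(
      data = data, aes(y = .data$speed_m_s), size = 0.6, alpha = 0.4
    )
  }
  p <- p +
    geom_line(aes(y = .data$mean), linetype = "dashed") +
    geom_line(
      data = dplyr::filter(object, .data$in_range), aes(y = .data$mean)
    ) +
    scale_x_log10() + scale_y_log10() +
    ggplot2::scale_colour_manual(values = mode_colours, aesthetics = c("colour", "fill")) +
    labs(x = "body mass (kg)", y = "travel speed (m/s)",
         colour = "mode", fill = "mode") +
    theme_minimal()
  p
}

#' Plot a model comparison
#'
#' Dot-and-whisker chart of each model's ELPD with +/- 2 SE of its
#' difference to the best model.
#'
#' @param object A `speed_comparison` from [compare_speed_models()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.speed_comparison <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$model <- factor(d$model, levels = rev(d$model))
  ggplot(d, aes(x = .data$elpd, y = .data$model)) +
    geom_pointrange(aes(xmin = .data$elpd - .data$se_delta / 2,
                        xmax = .data$elpd + .data$se_delta / 2)) +
    labs(x = "ELPD (leave-one-out)", y = NULL) +
    theme_minimal()
}

#' Plot posterior marginals of a fitted model
#'
#' Density of each parameter's posterior draws, faceted by parameter.
#'
#' @param object A `speed_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.speed_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$draws, -c(".chain", ".iteration"),
    names_to = "term", values_to = "value"
  )
  ggplot(long, aes(x = .data$value)) +
    ggplot2::geom_density() +
    facet_wrap(~term, scales = "free") +
    labs(x = NULL, y = "posterior density") +
    theme_minimal()
}
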