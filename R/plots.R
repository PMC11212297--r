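#' Plot a Monte Carlo power curve
#'
#' Power against sample size per engine, with a ribbon of +/- 2 Monte Carlo
#' standard errors and a dashed line at the target power.
#'
#' @param object An `rni_power_curve` from [power_curve()].
#' @param target_power Reference line (default 0.8).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rni_power_curve <- function(object, target_power = 0.8, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$n, y = .data$power,
    colour = .data$engine, fill = .data$engine
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = pmax(0, .data$power - 2 * .data$mc_se),
        ymax = pmin(1, .data$power + 2 * .data$mc_se)
      ),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = target_power, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "total visits simulated", y = "Monte Carlo power",
      colour = "engine", fill = "engine"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a minimum-sample-size search trace
#'
#' Every power evaluation the search made, in order, with the returned
#' minimum n marked.
#'
#' @param object An `rni_minn` from [min_sample_size()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rni_minn <- function(object, ...) {
  trace <- object$trace[[1]]
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$n, y = .data$power)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(0, .data$power - 2 * .data$mc_se),
      ymax = pmin(1, .data$power + 2 * .data$mc_se)
    )) +
    ggplot2::geom_hline(yintercept = object$target_power,
                        linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "total visits simulated (log scale)", y = "Monte Carlo power",
      title = paste0("minimum n: ", object$label)
    ) +
    ggplot2::theme_minimal()
  if (is.finite(object$n_min)) {
    p <- p + ggplot2::geom_vline(xintercept = object$n_min,
                                 linetype = "dotted")
  }
  p
}

#' Plot per-arm individual adverse-event proportions
#'
#' Bar chart of the individual event proportions in a stratum profile,
#' side by side per arm - the transparency view that should accompany any
#' combined-outcome comparison.
#'
#' @param profile An `rni_profile` from [stratum_profile()] whose stratum
#'   carried individual event indicator columns.
#' @return A ggplot object.
#' @export
plot_event_proportions <- function(profile) {
  if (!inherits(profile, "rni_profile") || nrow(profile$events) == 0L) {
    abort("`profile` has no individual event proportions to plot.")
  }
  ggplot2::ggplot(profile$events, ggplot2::aes(
    x = .data$event, y = .data$proportion, fill = .data$arm
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "event proportion", fill = "arm") +
    ggplot2::theme_minimal()
}
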