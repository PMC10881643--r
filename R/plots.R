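# ggplot2 figure methods for the result types.

#' Plot a simulated trajectory
#'
#' @param object An `sflt_trajectory`.
#' @param channels Which channels to draw.
#' @param ... Unused.
#' @return A ggplot object: molecules/cell over time, one line per channel.
#' @export
autoplot.sflt_trajectory <- function(object,
                                     channels = c("S_i", "S_x"), ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = dplyr::all_of(channels),
                              names_to = "channel", values_to = "amount")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$amount,
                                     colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "sFLT1 (molecules/cell)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an inhibition sweep
#'
#' @param object An `sflt_sweep` from [inhibition_sweep()].
#' @param ... Unused.
#' @return A ggplot of the extracellular ratio against fractional
#'   inhibition.
#' @export
autoplot.sflt_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$fraction_inhibition,
                               y = .data$extracellular_ratio)) +
    ggplot2::geom_line(colour = "darkorange") +
    ggplot2::labs(
      x = paste0("fraction inhibition of ", attr(object, "target_param")),
      y = sprintf("extracellular sFLT1 (%g h media, treated/control)",
                  attr(object, "duration"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a profile likelihood
#'
#' @param object An `sflt_profile` from [profile_likelihood()].
#' @param ... Unused.
#' @return A ggplot of the profile cost with the threshold line.
#' @export
autoplot.sflt_profile <- function(object, ...) {
  thr <- attr(object, "threshold") + min(object$profile_objective)
  gg <- ggplot2::ggplot(object, ggplot2::aes(x = .data$value,
                                             y = .data$profile_objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = attr(object, "param"), y = "profile cost") +
    ggplot2::theme_minimal()
  if (.log_scaled[[attr(object, "param")]]) gg <- gg + ggplot2::scale_x_log10()
  gg
}

#' Plot data against model predictions
#'
#' @param fit An `sflt_fit`.
#' @return A ggplot faceted by dataset and compartment, points for data and
#'   lines for the fitted predictions.
#' @export
plot_fit <- function(fit) {
  stopifnot(inherits(fit, "sflt_fit"))
  df <- fit$residuals
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$prediction),
                       colour = "darkorange") +
    ggplot2::facet_wrap(~ .data$experiment_id + .data$compartment,
                        scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "observed / predicted") +
    ggplot2::theme_minimal()
}
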