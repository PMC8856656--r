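#' Null distribution with the observed statistic
#'
#' Violin-and-point diagnostic for a Monte-Carlo verdict: the resampled
#' null as a density, the observed value as a point.
#'
#' @param object A `ca_mc_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ca_mc_test <- function(object, ...) {
  df <- tibble(value = object$null_values)
  ggplot2::ggplot(df, ggplot2::aes(x = object$label, y = .data$value)) +
    ggplot2::geom_violin(fill = "grey80", colour = NA) +
    ggplot2::geom_point(data = tibble(value = object$observed),
                        size = 3, colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "statistic",
                  subtitle = sprintf("p = %.3g %s", object$p_two,
                                     object$stars)) +
    ggplot2::theme_minimal()
}

#' Trial-aligned lick rate curves
#'
#' @param binned Output of [binned_lick_rate()], optionally row-bound over
#'   sessions with `mouse_id`/`day` columns.
#' @param windows [analysis_windows()] (drawn as CS/reward guides).
#' @return A ggplot of lick rate vs. time from CS onset.
#' @export
plot_lick_rate <- function(binned, windows = analysis_windows()) {
  p <- ggplot2::ggplot(binned, ggplot2::aes(x = .data$t, y = .data$rate))
  if ("day" %in% names(binned)) {
    p <- p + ggplot2::stat_summary(
      ggplot2::aes(colour = factor(.data$day)), fun = mean, geom = "line")
  } else {
    p <- p + ggplot2::geom_line()
  }
  p +
    ggplot2::annotate("rect", xmin = 0, xmax = windows$t_cs, ymin = -Inf,
                      ymax = Inf, alpha = 0.2) +
    ggplot2::geom_vline(xintercept = windows$t_cs + windows$t_delay,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "time from CS onset (s)", y = "lick rate (licks/s)",
                  colour = "day") +
    ggplot2::theme_minimal()
}

#' Cumulative reliability distributions
#'
#' The cumulative probability view used to compare response reliability
#' across days or cell types.
#'
#' @param rel A [reliability_table()] (pooled across mice).
#' @param stimulus Which stimulus to show.
#' @return A ggplot ECDF, one curve per day.
#' @export
plot_reliability_cdf <- function(rel, stimulus = "cs") {
  df <- rel %>% filter(.data$stimulus == !!stimulus)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reliability,
                                   colour = factor(.data$day))) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = sprintf("%s reliability index (%% of trials)", stimulus),
                  y = "cumulative probability", colour = "day") +
    ggplot2::theme_minimal()
}

#' Trial-averaged trace with stimulus periods
#'
#' @param avg A [trial_averaged_trace()] vector.
#' @param windows [analysis_windows()].
#' @param frame_rate Hz.
#' @return A ggplot of the aligned average with CS and reward periods shaded.
#' @export
plot_trial_average <- function(avg, windows = analysis_windows(),
                               frame_rate = 30) {
  t <- seq_along(avg) / frame_rate - windows$t_baseline
  anticipatory <- windows$t_cs + windows$t_delay
  ggplot2::ggplot(tibble(t = t, z = avg), ggplot2::aes(.data$t, .data$z)) +
    ggplot2::annotate("rect", xmin = 0, xmax = anticipatory, ymin = -Inf,
                      ymax = Inf, alpha = 0.15, fill = "steelblue") +
    ggplot2::annotate("rect", xmin = anticipatory,
                      xmax = anticipatory + windows$t_reward, ymin = -Inf,
                      ymax = Inf, alpha = 0.15, fill = "goldenrod") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from CS onset (s)", y = "z-scored dF") +
    ggplot2::theme_minimal()
}
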