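#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the likelihood curve of a census estimate
#'
#' @param object a `census_estimate`.
#' @param ... unused.
#' @return a ggplot: log-likelihood over candidate population sizes, with
#'   the point estimate marked.
#' @export
autoplot.census_estimate <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$loglik)) +
    ggplot2::geom_line(color = "grey30") +
    ggplot2::geom_vline(xintercept = object$n_hat, linetype = "dashed",
                        color = "firebrick") +
    ggplot2::labs(x = "candidate population size n",
                  y = "log likelihood",
                  title = paste0("Population size estimate: n = ",
                                 object$n_hat),
                  subtitle = paste0("T0 = ", signif(object$t0, 3),
                                    ", ", 100 * (1 - object$alpha),
                                    "% CI [1, ", signif(object$ci[2], 3),
                                    "]")) +
    ggplot2::theme_minimal()
}

#' Plot the per-size bootstrap null distributions of a census model
#'
#' @param object a `census_model`.
#' @param ... unused.
#' @return a ggplot of the null median and interquartile band of T against
#'   the number of contributors (log-log).
#' @export
autoplot.census_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$t_median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$t_q25,
                                      ymax = .data$t_q75),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(color = "steelblue4") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "number of contributors n",
                  y = "T statistic (median, IQR)",
                  title = "Bootstrap null distributions of T") +
    ggplot2::theme_minimal()
}

#' Plot benchmark predictions against the truth
#'
#' @param object a `census_benchmark`.
#' @param ... unused.
#' @return a ggplot of mean predicted size (with SD error bars) against the
#'   true size, with the identity line.
#' @export
autoplot.census_benchmark <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$actual,
                                   y = .data$mean_predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_predicted - .data$sd_predicted,
      ymax = .data$mean_predicted + .data$sd_predicted), width = 0.02) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "true population size",
                  y = "predicted population size (mean +/- SD)",
                  title = paste0("Simulation benchmark, MAPE = ",
                                 signif(object$mape, 3), "%")) +
    ggplot2::theme_minimal()
}

#' Plot sub-species diversity against aggregated population size
#'
#' @param curve the `curve` tibble from [diversity_vs_population()].
#' @return a ggplot with nucleotide diversity and polymorphic-site count
#'   (each normalized to its maximum) against population size.
#' @export
plot_diversity_curve <- function(curve) {
  df <- tidyr::pivot_longer(
    dplyr::transmute(curve, size = .data$size,
                     `nucleotide diversity` =
                       .data$mean_pi / max(.data$mean_pi),
                     `polymorphic sites` =
                       .data$mean_polymorphic / max(.data$mean_polymorphic)),
    -"size", names_to = "metric", values_to = "relative")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$relative,
                                   color = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "aggregated population size",
                  y = "fraction of maximum",
                  color = NULL,
                  title = "Sub-species diversity vs population size") +
    ggplot2::theme_minimal()
}
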