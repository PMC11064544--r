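# Optional ggplot2 graphics for the forest and pcVPC summaries.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package")
}

#' Forest plot of simulated covariate effects
#'
#' Normalised geometric-mean exposure ratios (median and 2.5th/97.5th
#' percentiles over trials) per covariate category, with the 0.8-1.25
#' bioequivalence band shaded.
#'
#' @param x a `forest_summary` from [forest_simulation()].
#' @param metric which exposure metric to show.
#' @return a ggplot object.
#' @export
plot_forest <- function(x, metric = c("auc", "cmax", "ctau")) {
  need_ggplot()
  metric <- match.arg(metric)
  df <- x$summary[x$summary$metric == metric &
                    x$summary$category != "overall", ]
  df$label <- paste(df$covariate, df$category, sep = " ")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$median, y = .data$label)) +
    ggplot2::annotate("rect", xmin = 0.8, xmax = 1.25, ymin = -Inf,
                      ymax = Inf, alpha = 0.15, fill = "grey40") +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("Fold change in %s vs overall population",
                              toupper(metric)),
                  y = NULL)
}

#' Plot a prediction-corrected visual predictive check
#'
#' Observed median (solid) and 5th/95th percentiles (dashed) per time bin
#' over the simulation-based confidence bands.
#'
#' @param x a `pcvpc_result` from [pcvpc()].
#' @return a ggplot object.
#' @export
plot_pcvpc <- function(x) {
  need_ggplot()
  b <- x$bins
  ggplot2::ggplot(b, ggplot2::aes(x = .data$t_mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p50_lo, ymax = .data$p50_hi),
                         fill = "red", alpha = 0.2) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p5_lo, ymax = .data$p5_hi),
                         fill = "blue", alpha = 0.2) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p95_lo, ymax = .data$p95_hi),
                         fill = "blue", alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p50), colour = "red") +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p5), colour = "red",
                       linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p95), colour = "red",
                       linetype = 2) +
    ggplot2::labs(x = "Time after dose (h)",
                  y = "Prediction-corrected concentration (ug/mL)")
}
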