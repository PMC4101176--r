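# ggplot2 presentation layer. Every plot function takes the tibble its
# companion computation returns, so results pipe straight into a figure.

#' Stacked ancestry bar plot
#'
#' The classic structure-style plot: one bar per individual, filled by
#' ancestry proportion.
#'
#' @param object an `ancestry_fit`.
#' @param pop_labels optional per-sample labels used to facet the bars.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ancestry_fit <- function(object, pop_labels = NULL, ...) {
  df <- generics::tidy(object)
  df$sample <- factor(df$sample, levels = rownames(object$Q))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$sample, .data$proportion,
                                        fill = .data$ancestry)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "ancestry proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
  if (!is.null(pop_labels)) {
    df$group <- rep(pop_labels, times = ncol(object$Q))
    p <- p %+% df + ggplot2::facet_grid(~group, scales = "free_x",
                                        space = "free_x")
  }
  p
}

#' Plot panel-evaluation summaries
#'
#' Mean focal ancestry with 95% interval, by panel size and population —
#' the visual of how estimates degrade as panels shrink.
#'
#' @param summary a tibble from [rsnp_resampling()] (or stacked
#'   [evaluate_panel()] rows with a `panel_size` column).
#' @return A ggplot object.
#' @export
plot_eval_summary <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(factor(.data$panel_size), .data$mean,
                               colour = .data$group)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high),
                             position = ggplot2::position_dodge(0.4)) +
    ggplot2::facet_wrap(~ancestry) +
    ggplot2::labs(x = "panel size (loci)", y = "focal ancestry",
                  colour = "population") +
    ggplot2::theme_minimal()
}

#' Plot ancestry error against panel size
#'
#' Error (RMS deviation from the genome-wide reference) versus panel size,
#' one line per ancestry component; solid/dashed distinguishes unadmixed
#' from admixed genomes when both are present.
#'
#' @param errors stacked [panel_error()] reports.
#' @return A ggplot object.
#' @export
plot_error_vs_size <- function(errors) {
  ggplot2::ggplot(errors,
                  ggplot2::aes(.data$panel_size, .data$error,
                               colour = .data$ancestry,
                               linetype = .data$admixed)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "panel size (loci, log scale)",
                  y = "error (RMS about reference ancestry)") +
    ggplot2::theme_minimal()
}

#' Plot the sample-size experiment
#'
#' Mean population ancestry with bootstrap interval as a function of
#' sub-sample size.
#'
#' @param summary a tibble from [sample_size_experiment()].
#' @return A ggplot object.
#' @export
plot_size_experiment <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(.data$size, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "sub-sample size (individuals)",
                  y = "mean own-population ancestry") +
    ggplot2::theme_minimal()
}

#' Plot a principal-coordinate map
#'
#' @param coords a tibble from [pca_from_ibs()].
#' @return A ggplot object.
#' @export
plot_pca <- function(coords) {
  ggplot2::ggplot(coords, ggplot2::aes(.data$PC1, .data$PC2,
                                       colour = .data$population)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(colour = "population") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 %+%
NULL
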