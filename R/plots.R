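# autoplot() methods for the main result types.

#' Plot a secretion profile
#'
#' Bar chart of maximum net secretion capacities per metabolite.
#'
#' @param object a `secretion_profile`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot secretion_profile
#' @export
autoplot.secretion_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$metabolite,
                                                  .data$max_secretion),
                               y = .data$max_secretion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "max net secretion (mmol/person/day)",
                  title = "Community secretion capacities") +
    ggplot2::theme_minimal()
}

#' Plot flux variability intervals
#'
#' One horizontal segment per reaction spanning its feasible flux range.
#'
#' @param object an `fva_result`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot fva_result
#' @export
autoplot.fva_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(y = .data$reaction)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$min_flux,
                                       xend = .data$max_flux,
                                       yend = .data$reaction),
                          linewidth = 2, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "flux (mmol/person/day)", y = NULL,
                  title = "Flux variability") +
    ggplot2::theme_minimal()
}

#' Plot a co-metabolism decomposition
#'
#' Bars for the germ-free maximum, the direct microbial secretion and the
#' co-metabolism residual stacking up to the personalised maximum.
#'
#' @param object a `cometab_report`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot cometab_report
#' @export
autoplot.cometab_report <- function(object, ...) {
  parts <- tibble::tibble(
    component = factor(c("germ-free", "microbial secretion", "co-metabolism"),
                       levels = c("co-metabolism", "microbial secretion",
                                  "germ-free")),
    flux = c(object$germfree_max, object$microbial_secretion_max,
             object$cometabolism_residual))
  ggplot2::ggplot(parts, ggplot2::aes(x = "personalised maximum",
                                      y = .data$flux,
                                      fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "urine secretion (mmol/person/day)",
                  title = paste0("Urine ", object$metabolite,
                                 " secretion decomposition")) +
    ggplot2::theme_minimal()
}

#' Plot a knockout screen
#'
#' Lollipop chart of the fractional reduction per deleted reaction, with the
#' flag threshold marked.
#'
#' @param object a `knockout_report`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot knockout_report
#' @export
autoplot.knockout_report <- function(object, ...) {
  d <- object$results
  ggplot2::ggplot(d, ggplot2::aes(x = .data$reduction_fraction,
                                  y = stats::reorder(.data$reaction,
                                                     .data$reduction_fraction),
                                  colour = .data$flagged)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$reduction_fraction,
                                       yend = stats::reorder(
                                         .data$reaction,
                                         .data$reduction_fraction))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = object$flag_threshold, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "fractional reduction of target flux", y = NULL,
                  title = "Single-reaction knockout screen") +
    ggplot2::theme_minimal()
}

#' Plot per-sample log ratios by group
#'
#' @param log_ratio result of [log_ratio_test()].
#' @return A ggplot (boxplot + jitter).
#' @export
plot_log_ratio <- function(log_ratio) {
  ggplot2::ggplot(log_ratio$samples,
                  ggplot2::aes(x = .data$group, y = .data$log_ratio)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "log(up-set counts / down-set counts)",
                  title = "Compositional log-ratio by group") +
    ggplot2::theme_minimal()
}
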