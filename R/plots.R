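#' Ratio-by-group figure
#'
#' Box-and-jitter plot of a per-cell derived quantity by acclimation group,
#' with per-male means overlaid as filled points - the standard display for
#' a cell-level measure with male-level structure.
#'
#' @param derived Per-cell derived morphometry with `group` and `male_id`.
#' @param measure Column to plot (default the flagellum-to-head-surface-area
#'   ratio).
#' @return A ggplot object.
#' @export
plot_ratio_by_group <- function(derived, measure = "ratio_LF_AH_per_um") {
  check_columns(derived, c("group", "male_id", measure))
  male_means <- derived %>%
    group_by(.data$group, .data$male_id) %>%
    summarise(value = mean(.data[[measure]]), .groups = "drop")
  ggplot2::ggplot(derived,
                  ggplot2::aes(x = .data$group, y = .data[[measure]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.25, colour = "grey50",
                         size = 0.8) +
    ggplot2::geom_point(data = male_means,
                        ggplot2::aes(y = .data$value),
                        size = 2.2, colour = "black") +
    ggplot2::labs(x = "Acclimation group", y = measure) +
    ggplot2::theme_classic()
}

#' Coefficient plot for a fitted comparison
#'
#' Dot-and-whisker display of term estimates with approximate 95% intervals
#' (estimate +/- 1.96 standard errors).
#'
#' @param object A [sperm_fit].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sperm_fit
#' @export
autoplot.sperm_fit <- function(object, ...) {
  t <- tidy(object) %>%
    filter(.data$term != "(Intercept)") %>%
    mutate(lo = .data$estimate - 1.96 * .data$std_error,
           hi = .data$estimate + 1.96 * .data$std_error)
  ggplot2::ggplot(t, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(title = object$stage, x = "Estimate", y = NULL) +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
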