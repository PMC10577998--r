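#' Forest plot of MSM contrasts
#'
#' Mean log differences versus the reference level with 95% confidence
#' intervals; entries whose interval excludes zero are highlighted.
#'
#' @param object A `msm_contrasts` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot msm_contrasts
#' @export
autoplot.msm_contrasts <- function(object, ...) {
  d <- tidy(object)
  d$level <- factor(d$level, levels = rev(unique(d$level)))
  d$significant <- d$conf.low > 0 | d$conf.high < 0
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$level,
                                  color = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        color = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey30",
                                           `TRUE` = "#b2182b"),
                                guide = "none") +
    ggplot2::labs(x = sprintf("Mean log difference vs. %s (95%% CI)",
                              d$reference[1]),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of a study's sensitivity grid
#'
#' One row per level, faceted by trimming percentile and outlier setting.
#'
#' @param object An `ecotmle_study`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ecotmle_study
#' @export
autoplot.ecotmle_study <- function(object, ...) {
  d <- contrast_table(object)
  d$level <- factor(d$level, levels = rev(unique(d$level)))
  d$significant <- d$conf.low > 0 | d$conf.high < 0
  d$trim_label <- sprintf("trim %gth pct", d$trim_percentile)
  d$trim_label <- factor(d$trim_label, levels = unique(d$trim_label))
  d$outlier_label <- ifelse(d$outliers_removed, "outliers removed",
                            "all rows")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$level,
                                  color = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        color = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey30",
                                           `TRUE` = "#b2182b"),
                                guide = "none") +
    ggplot2::facet_grid(outlier_label ~ trim_label) +
    ggplot2::labs(x = sprintf("Mean log difference vs. %s (95%% CI)",
                              d$reference[1]),
                  y = NULL) +
    ggplot2::theme_minimal()
}
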