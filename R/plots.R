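# ggplot2 methods for the result containers.

#' @importFrom ggplot2 autoplot ggplot aes
#' @export
ggplot2::autoplot

#' Plot group time courses
#'
#' Mean +/- SEM curves per dose-rate group, one panel per dose.
#'
#' @param object A `flash_curve` from [group_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.flash_curve <- function(object, ...) {
  quantity <- attr(object, "quantity") %||% "value"
  ylab <- if (identical(quantity, "swelling")) {
    "Ear swelling (µm, vs sham mean)"
  } else {
    "Inflammation score"
  }
  ggplot(object, aes(x = .data$day, y = .data$mean,
                     colour = .data$dose_rate_label,
                     fill = .data$dose_rate_label)) +
    ggplot2::geom_ribbon(aes(ymin = .data$mean - .data$sem,
                             ymax = .data$mean + .data$sem),
                         alpha = 0.2, colour = NA, na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$dose_Gy),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Days after irradiation", y = ylab,
                  colour = "Dose rate", fill = "Dose rate") +
    ggplot2::theme_minimal()
}

#' Plot a group comparison
#'
#' The underlying group curves with each group's peak marked.
#'
#' @param object A `flash_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.flash_comparison <- function(object, ...) {
  autoplot(object$curves) +
    ggplot2::geom_point(
      data = object$peaks,
      aes(x = .data$peak_day, y = .data$peak_mean,
          colour = .data$dose_rate_label),
      shape = 18, size = 3, inherit.aes = FALSE
    )
}

#' Plot blood-volume estimates
#'
#' Irradiated volume per irradiation mode with the static component overlaid,
#' on a log scale (the modes span two orders of magnitude).
#'
#' @param object A `blood_volume_estimate` from [estimate_blood_volume()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.blood_volume_estimate <- function(object, ...) {
  ggplot(object, aes(x = .data$label)) +
    ggplot2::geom_col(aes(y = .data$irradiated_ul), fill = "steelblue",
                      width = 0.6) +
    ggplot2::geom_col(aes(y = .data$static_ul), fill = "grey40", width = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "Irradiated blood volume (µl, log scale)",
                  caption = "dark: static component; blue: total irradiated") +
    ggplot2::theme_minimal()
}

#' Plot a log2 fold-change summary
#'
#' Mean log2 FC bars with SD error bars per gene, group and sampling day.
#'
#' @param summary A summary tibble from [summarize_log2fc()].
#' @return A ggplot.
#' @export
plot_log2fc <- function(summary) {
  check_columns(summary, c("gene", "group", "day", "mean_log2_fc"),
                "log2FC summary")
  ggplot(summary, aes(x = factor(.data$day), y = .data$mean_log2_fc,
                      fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      aes(ymin = .data$mean_log2_fc - .data$sd_log2_fc,
          ymax = .data$mean_log2_fc + .data$sd_log2_fc),
      position = ggplot2::position_dodge(0.8), width = 0.25, na.rm = TRUE
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Days after irradiation", y = "log2 fold change",
                  fill = "Group") +
    ggplot2::theme_minimal()
}
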