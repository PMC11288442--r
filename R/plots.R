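#' Plot simulated or measured displacement traces with stride boundaries
#'
#' @param traces Trace tibble (`time_s`, `head_z_mm`, `pelvis_z_mm`).
#' @param strides Optional stride table from [segment_strides()]; stride
#'   starts are drawn as vertical lines.
#' @param max_time Truncate the plot after this many seconds (default 5).
#' @return A ggplot object.
#' @export
plot_traces <- function(traces, strides = NULL, max_time = 5) {
  d <- traces |>
    dplyr::filter(.data$time_s <= max_time) |>
    tidyr::pivot_longer(dplyr::all_of(c("head_z_mm", "pelvis_z_mm")),
                        names_to = "location", values_to = "z_mm") |>
    dplyr::mutate(location = sub("_z_mm", "", .data$location))
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$z_mm)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~location, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "vertical displacement (mm)") +
    ggplot2::theme_minimal()
  if (!is.null(strides)) {
    starts <- strides$start_s[strides$start_s <= max_time]
    p <- p + ggplot2::geom_vline(xintercept = starts, linetype = 3,
                                 colour = "grey50")
  }
  p
}

#' Boxplot of Total Asymmetry Score by perceived sidedness grade
#'
#' The study-style figure for the graded sidedness question: TAS
#' distributions per group with the raw values overlaid.
#'
#' @param data Data frame with one row per horse.
#' @param tas,grade Column names (tidy-eval) of the TAS (mm) and the
#'   sidedness factor.
#' @return A ggplot object.
#' @export
plot_tas_by_sidedness <- function(data, tas, grade) {
  ggplot2::ggplot(data, ggplot2::aes({{ grade }}, {{ tas }})) +
    ggplot2::geom_boxplot(outlier.shape = 16, outlier.size = 2) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", linetype = 2,
                          linewidth = 0.3, width = 0.6) +
    ggplot2::geom_jitter(width = 0.1, size = 0.8, alpha = 0.5) +
    ggplot2::labs(x = "rider-perceived sidedness",
                  y = "total asymmetry score (mm)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.equisym_assoc <- function(object, ...) {
  if (is.null(object$emmeans)) {
    abort("fit has no marginal means (refit with contrasts = TRUE)",
          class = "equisym_input_error")
  }
  ggplot2::ggplot(object$emmeans,
                  ggplot2::aes(.data$group, .data$emmean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower.CL,
                                          ymax = .data$upper.CL)) +
    ggplot2::labs(
      x = "group", y = "estimated marginal mean",
      caption = if (object$transformation == "boxcox") {
        sprintf("Box-Cox transformed scale (lambda = %.2f)", object$lambda)
      } else NULL
    ) +
    ggplot2::theme_minimal()
}
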