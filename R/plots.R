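#' Plot the variance statistic with detected windows
#'
#' Shows the rolling variance statistic over time on a log-friendly scale
#' with the detected SPT windows shaded and the per-day threshold drawn, the
#' standard visual check of a detection run.
#'
#' @param var_stat an [epoch_series()] of kind `"var_stat"`.
#' @param windows optional windows tibble to overlay.
#' @return A ggplot object.
#' @export
plot_detection <- function(var_stat, windows = NULL) {
  p <- ggplot2::ggplot(var_stat, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "grey30") +
    ggplot2::labs(x = NULL, y = "z-angle change statistic (deg)") +
    ggplot2::theme_minimal()
  if (!is.null(windows)) {
    w <- windows[!is.na(windows$onset), , drop = FALSE]
    if (nrow(w)) {
      p <- p +
        ggplot2::geom_rect(
          data = w, inherit.aes = FALSE,
          ggplot2::aes(xmin = .data$onset, xmax = .data$wake,
                       ymin = -Inf, ymax = Inf),
          fill = "steelblue", alpha = 0.2
        ) +
        ggplot2::geom_segment(
          data = w, inherit.aes = FALSE,
          ggplot2::aes(x = .data$onset, xend = .data$wake,
                       y = .data$threshold_used_deg,
                       yend = .data$threshold_used_deg),
          colour = "firebrick", linetype = 2
        )
    }
  }
  p
}

#' @rdname compare_diary
#' @param object a `diary_comparison` object.
#' @exportS3Method ggplot2::autoplot
autoplot.diary_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$nights,
    cols = c("onset_diff", "wake_diff", "duration_diff"),
    names_to = "parameter", values_to = "diff_min"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$diff_min)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "diary - algorithm (minutes)", y = "nights") +
    ggplot2::theme_minimal()
}

#' @rdname compare_psg
#' @param object a `psg_comparison` object.
#' @exportS3Method ggplot2::autoplot
autoplot.psg_comparison <- function(object, ...) {
  ggplot2::ggplot(object$stages,
                  ggplot2::aes(x = .data$stage, y = .data$sensitivity_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = "sleep stage",
                  y = "epochs inside detected window (%)") +
    ggplot2::theme_minimal()
}
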