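#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an aggregated series
#'
#' Line-and-point plot of the per-day or per-phase means produced by
#' [aggregate_observations()], coloured by phase type — the plot a results
#' screen would show.
#'
#' @param object A `nof1_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nof1_series <- function(object, ...) {
  grain <- attr(object, "grain")
  df <- as.data.frame(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$mean)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$phase_label, size = .data$n)) +
    ggplot2::scale_size_continuous(range = c(1.5, 4)) +
    ggplot2::labs(
      x = if (grain == "day") "trial day" else "phase",
      y = "mean value",
      colour = "phase",
      title = paste0("Measure ", attr(object, "measure_id"), " by ", grain)
    ) +
    ggplot2::theme_minimal()
}

#' Plot raw observations with phase shading
#'
#' Scatter of every recorded value over trial days, with the A/B phase
#' structure shaded in the background.
#'
#' @param log An observation tibble.
#' @param spec A valid `nof1_trial`.
#' @param measure_id A numeric (keyboard or scale) measure id.
#' @return A ggplot object.
#' @export
plot_observations <- function(log, spec, measure_id) {
  numeric_measure(spec, measure_id)
  obs <- log[log$measure_id == measure_id, , drop = FALSE]
  obs$.value <- observation_values(obs)
  cal <- phase_calendar(spec$schedule)
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = cal,
      ggplot2::aes(xmin = .data$start_day - 0.5, xmax = .data$end_day + 0.5,
                   ymin = -Inf, ymax = Inf, fill = .data$label),
      alpha = 0.15
    ) +
    ggplot2::geom_point(
      data = obs,
      ggplot2::aes(x = .data$day_index, y = .data$.value)
    ) +
    ggplot2::labs(x = "trial day", y = "value", fill = "phase") +
    ggplot2::theme_minimal()
}
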