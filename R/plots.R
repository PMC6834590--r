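# ggplot2 helpers for traces, bouts, and state summaries.

#' Plot an activity trace with detected bouts
#'
#' @param trace A tibble from [activity_trace()] (columns `time_s`,
#'   `normalized`).
#' @param bouts Optional `bout_set`; detected bouts are shaded.
#' @param threshold Optional horizontal threshold line; defaults to the
#'   bout set's threshold when `bouts` is given.
#' @return A ggplot object.
#' @export
plot_activity_trace <- function(trace, bouts = NULL, threshold = NULL) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$time_s / 60,
                                           y = .data$normalized)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (min)", y = "Normalized activity")
  if (!is.null(bouts) && nrow(bouts) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(bouts),
      ggplot2::aes(xmin = .data$start_s / 60, xmax = .data$end_s / 60),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "steelblue", alpha = 0.25
    )
  }
  threshold <- threshold %||% if (!is.null(bouts)) attr(bouts, "threshold")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                                 colour = "grey40")
  }
  p + ggplot2::theme_classic()
}

#' Raster plot of sleep bouts across animals
#'
#' One row per animal, with each detected bout drawn as a filled segment —
#' the standard way to show bout structure across a population.
#'
#' @param bouts A `bout_set`, a list of them, or a tidy bout table with
#'   `animal_id`, `start_s`, `end_s`.
#' @return A ggplot object.
#' @export
plot_bout_raster <- function(bouts) {
  tab <- if (inherits(bouts, "bout_set")) {
    tidy(bouts)
  } else if (is.data.frame(bouts)) {
    as_tibble(bouts)
  } else {
    purrr::map_dfr(bouts, tidy)
  }
  ggplot2::ggplot(tab) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$start_s / 60, xmax = .data$end_s / 60,
                   ymin = as.integer(factor(.data$animal_id)) - 0.4,
                   ymax = as.integer(factor(.data$animal_id)) + 0.4),
      fill = "grey20"
    ) +
    ggplot2::scale_y_continuous(
      breaks = seq_along(unique(tab$animal_id)),
      labels = unique(tab$animal_id)
    ) +
    ggplot2::labs(x = "Time (min)", y = NULL) +
    ggplot2::theme_classic()
}

#' @rdname plot_bout_raster
#' @param object A `bout_set`.
#' @param ... Unused.
#' @method autoplot bout_set
#' @export
autoplot.bout_set <- function(object, ...) {
  plot_bout_raster(object)
}

#' Plot a fluorescence trace against behavior
#'
#' @param fluor A `fluor_trace` or `ratio_trace` (column `dFF` or `dRR`).
#' @param behavior Optional tibble with `time_s`, `normalized` drawn as a
#'   second panel variable.
#' @return A ggplot object.
#' @export
plot_fluor_trace <- function(fluor, behavior = NULL) {
  ycol <- if ("dRR" %in% names(fluor)) "dRR" else "dFF"
  tab <- tibble(time_s = fluor$time_s, value = fluor[[ycol]],
                series = ycol)
  if (!is.null(behavior)) {
    tab <- dplyr::bind_rows(tab, tibble(
      time_s = behavior$time_s, value = behavior$normalized,
      series = "behavior"
    ))
  }
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$time_s / 60, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~series, ncol = 1L, scales = "free_y") +
    ggplot2::labs(x = "Time (min)", y = NULL) +
    ggplot2::theme_classic()
}
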