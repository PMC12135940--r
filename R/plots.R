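#' @describeIn stimulus_bias Heat map of the per-unit bias series, units
#'   ordered by their mean response-window bias.
#' @param object A `wb_bias` tibble.
#' @param ... Unused.
#' @export
autoplot.wb_bias <- function(object, ...) {
  s <- summarize_bias(object)
  ord <- s$unit_id[order(s$mean_response)]
  df <- object
  df$unit_id <- factor(df$unit_id, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time * 1000, y = .data$unit_id,
                                   fill = .data$dprime)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "Time from first touch (ms)", y = NULL,
                  fill = "Stimulus bias (d')") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @describeIn xcorr_min_lag Mean cross-correlogram with the summary lag
#'   marked.
#' @param object A `wb_lag`.
#' @export
autoplot.wb_lag <- function(object, ...) {
  ggplot2::ggplot(object$correlogram,
                  ggplot2::aes(x = .data$lag * 1000, y = .data$r)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$summary_lag * 1000,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "Lag (ms)", y = "Mean cross-correlation",
                  subtitle = sprintf("mean minimum-correlation lag %.1f ms",
                                     1000 * object$summary_lag)) +
    ggplot2::theme_minimal()
}

#' Population PSTH plot by condition
#'
#' Mean rate over units and trials for each trial subset, against time from
#' the alignment event.
#'
#' @param tensor A [rate_tensor()] (typically z-scored).
#' @param conditions Named list of logical/integer trial subsets.
#' @param units Optional unit-id subset.
#' @return A ggplot.
#' @export
plot_population_psth <- function(tensor, conditions, units = NULL) {
  dfs <- lapply(names(conditions), function(nm) {
    p <- psth(tensor, trials = conditions[[nm]])
    if (!is.null(units)) p <- p[p$unit_id %in% units, ]
    p |>
      dplyr::group_by(.data$time) |>
      dplyr::summarise(rate = mean(.data$rate, na.rm = TRUE), .groups = "drop") |>
      dplyr::mutate(condition = nm)
  })
  ggplot2::ggplot(dplyr::bind_rows(dfs),
                  ggplot2::aes(x = .data$time * 1000, y = .data$rate,
                               colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "Time from first touch (ms)", y = "Rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
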