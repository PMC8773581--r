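# ggplot2 displays for spectrograms, AUC maps and trends.

#' @export
autoplot.eeg_dsa <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$freq_hz,
                                       fill = power_db(.data$power))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)",
                  title = "Density spectral array") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.auc_map <- function(object, ...) {
  df <- dplyr::mutate(as_tibble(as.data.frame(object)),
                      cluster_edge = ifelse(.data$cluster, 1, 0))
  ggplot2::ggplot(df, ggplot2::aes(.data$rel_time_s, .data$freq_hz)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$auc)) +
    ggplot2::geom_point(data = dplyr::filter(df, .data$cluster),
                        shape = 15, size = 0.6, colour = "black") +
    ggplot2::scale_fill_gradient2(midpoint = 0.5, limits = c(0, 1),
                                  low = "blue", mid = "white",
                                  high = "red", name = "AUC") +
    ggplot2::labs(x = "time relative to ROR (s)", y = "frequency (Hz)",
                  title = "Pixel-wise AUC map (clusters marked)") +
    ggplot2::theme_minimal()
}

#' Plot a parameter trend with its event markers
#'
#' @param trend A trend tibble from [peen_trend()], [index_trend()] or
#'   [band_power()].
#' @param value_col Column plotted; defaults to the first numeric non-time
#'   column.
#' @return A ggplot object.
#' @export
plot_trend <- function(trend, value_col = NULL) {
  if (is.null(value_col)) {
    value_col <- setdiff(names(trend)[vapply(trend, is.numeric,
                                             logical(1))], "time_s")[1]
  }
  ev <- attr(trend, "events") %||% numeric()
  p <- ggplot2::ggplot(trend, ggplot2::aes(.data$time_s,
                                           .data[[value_col]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = value_col) +
    ggplot2::theme_minimal()
  if (length(ev)) {
    p <- p + ggplot2::geom_vline(xintercept = as.numeric(ev),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Connected-dot plot of a paired transition set
#'
#' Mirrors the pre/post connected-dot-and-box display used for transition
#' statistics: one line per subject from the pre-event to the post-event
#' value.
#'
#' @param pset A `paired_transition_set` from [build_paired_set()].
#' @return A ggplot object.
#' @export
plot_paired_set <- function(pset) {
  df <- tidyr::pivot_longer(as_tibble(as.data.frame(pset)),
                            c("pre", "post"), names_to = "side") |>
    dplyr::mutate(side = factor(.data$side, levels = c("pre", "post")))
  ggplot2::ggplot(df, ggplot2::aes(.data$side, .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject_id),
                       alpha = 0.4) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = NULL,
                  y = attr(pset, "parameter") %||% "value",
                  title = attr(pset, "event_name") %||% "transition") +
    ggplot2::theme_minimal()
}

#' Box plot of wake-like index durations by group
#'
#' @param durations Tibble from [duration_above()] rows (columns `group`,
#'   `duration_s`).
#' @return A ggplot object.
#' @export
plot_durations <- function(durations) {
  ggplot2::ggplot(durations, ggplot2::aes(.data$group, .data$duration_s)) +
    ggplot2::geom_boxplot(width = 0.5) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "index >= 80 duration before ROR (s)") +
    ggplot2::theme_minimal()
}
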