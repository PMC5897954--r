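# ggplot2 graphics for arrays, campaigns, localizations and model fits.

#' Map of a campaign design
#'
#' Recorder positions and broadcast sites on the study plane.
#'
#' @param array A [build_grid_array()] table.
#' @param sites Optional site table from [sample_broadcast_sites()].
#' @return A ggplot.
#' @export
plot_campaign_map <- function(array, sites = NULL) {
  units <- as_tibble(array) %>%
    group_by(.data$recorder_id) %>%
    summarise(x = mean(.data$x), y = mean(.data$y), .groups = "drop")
  p <- ggplot2::ggplot(units, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(shape = 17, size = 3, colour = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)")
  if (!is.null(sites)) {
    p <- p + ggplot2::geom_point(
      data = sites, ggplot2::aes(colour = .data$stratum), size = 1.8
    )
  }
  p
}

#' @method autoplot toa_localization
#' @export
autoplot.toa_localization <- function(object, ...) {
  mics <- as_tibble(object$toaset)
  est <- tibble(x = object$x, y = object$y)
  ggplot2::ggplot(mics, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(shape = 17, size = 3, colour = "firebrick") +
    ggplot2::geom_point(data = est, shape = 4, size = 4, stroke = 1.5,
                        colour = "navy") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (m)", y = "y (m)",
      title = sprintf("%s: temporal error %.1f ms",
                      object$broadcast_id, object$temporal_error_ms)
    )
}

#' Accuracy against temporal error
#'
#' Scatter of localization accuracy vs the temporal-error reliability
#' statistic, with the reliability threshold marked — the diagnostic used
#' to justify discarding high-temporal-error estimates.
#'
#' @param records Evaluation records with `loc_accuracy` and
#'   `temporal_error_ms`.
#' @param threshold_ms Threshold to draw, ms.
#' @return A ggplot.
#' @export
plot_accuracy_error <- function(records, threshold_ms = 200) {
  ggplot2::ggplot(records, ggplot2::aes(
    x = .data$temporal_error_ms, y = .data$loc_accuracy
  )) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$array)) +
    ggplot2::geom_vline(xintercept = threshold_ms, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "temporal error (ms)", y = "localization accuracy (m)")
}

#' @method autoplot accuracy_models
#' @export
autoplot.accuracy_models <- function(object, ...) {
  cmp <- object$comparison %>%
    mutate(model = factor(.data$model, levels = rev(.data$model)))
  ggplot2::ggplot(cmp, ggplot2::aes(x = .data$aic, y = .data$model)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = "AIC", y = NULL)
}
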