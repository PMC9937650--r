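#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot observed vs fitted log-odds of a decomposition
#'
#' Points are the target curve's log-odds at each test point; the line is
#' the fitted non-negative combination of driver log-odds.
#'
#' @param object A `pi_decomposition` from [nnls_decompose()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pi_decomposition
#' @export
autoplot.pi_decomposition <- function(object, ...) {
  df <- object$fitted |>
    dplyr::mutate(point = dplyr::row_number(),
                  phase = factor(.data$phase, levels = unique(.data$phase)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$point)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$r_observed,
                                     colour = .data$phase)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$r_fitted)) +
    ggplot2::labs(x = "test point", y = "log-odds R",
                  colour = "phase",
                  title = "Observed (points) vs fitted (line) log-odds") +
    ggplot2::theme_minimal()
}

#' Plot a trial-averaged dF/F trace
#'
#' Thin lines are individual trials; the thick line is the trial mean. A
#' dashed vertical line marks stimulation onset.
#'
#' @param object A `dff_result` from [delta_f_over_f()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dff_result
#' @export
autoplot.dff_result <- function(object, ...) {
  ggplot2::ggplot(object$trials,
                  ggplot2::aes(x = .data$time_s, y = .data$dff,
                               group = .data$trial)) +
    ggplot2::geom_line(alpha = 0.25) +
    ggplot2::geom_line(data = object$mean, ggplot2::aes(group = NULL),
                       linewidth = 1) +
    ggplot2::geom_vline(xintercept = object$onset, linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = expression(Delta * F / F)) +
    ggplot2::theme_minimal()
}

#' Input/output scatter of candidate interneurons
#'
#' One point per candidate cell type: synapses received from the source
#' MBON against synapses sent to the target DANs, outliers labelled.
#'
#' @param scatter Output of [input_output_scatter()].
#' @return A ggplot.
#' @export
plot_io_scatter <- function(scatter) {
  ggplot2::ggplot(scatter, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outlier)) +
    ggplot2::geom_text(data = scatter |> dplyr::filter(.data$outlier),
                       ggplot2::aes(label = .data$cell_type),
                       vjust = -0.8, size = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "inputs from source MBON (synapses)",
                  y = "outputs to target DANs (synapses)",
                  colour = "outlier") +
    ggplot2::theme_minimal()
}

#' Plot performance-index curves across protocol phases
#'
#' @param curves Tibble with columns `phase`, `trial`, `pi` and optionally
#'   `driver` (one line per driver).
#' @return A ggplot with test points in protocol order, shaded by phase.
#' @export
plot_pi_curves <- function(curves) {
  curves <- curves |>
    dplyr::mutate(phase = factor(.data$phase, levels = unique(.data$phase)))
  has_driver <- "driver" %in% names(curves)
  key <- if (has_driver) curves$driver else "composite"
  curves <- curves |>
    dplyr::mutate(driver = key) |>
    dplyr::arrange(.data$driver, .data$phase, .data$trial) |>
    dplyr::mutate(point = dplyr::row_number(), .by = "driver")
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$point, y = .data$pi,
                                       colour = .data$driver)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(. ~ phase, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "test point (protocol order)", y = "performance index") +
    ggplot2::theme_minimal()
}
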