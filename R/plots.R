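# Plot methods. All plots are ggplot2 objects the caller can style further.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a baseline concentration sweep
#'
#' Baseline EDL potential and ionic current against concentration, one panel
#' each, log-scaled concentration axis.
#'
#' @param object A tibble from [baseline_sweep()] (optionally with an
#'   `electrolyte` column to colour by).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot baseline_sweep
#' @export
autoplot.baseline_sweep <- function(object, ...) {
  plot_baseline_sweep(object)
}

#' @rdname autoplot.baseline_sweep
#' @param sweep Sweep tibble.
#' @export
plot_baseline_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(sweep, c("V_bs_mV", "I_bs_nA"),
                              names_to = "quantity", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$conc_M, y = .data$value))
  if ("electrolyte" %in% names(sweep))
    p <- p + ggplot2::aes(colour = .data$electrolyte)
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "concentration (M)", y = NULL)
}

#' Plot a current trace with extracted events
#'
#' @param object A `current_trace`.
#' @param events Optional event table from [extract_events()]; detected
#'   peaks are marked.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot current_trace
#' @export
autoplot.current_trace <- function(object, events = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                            y = .data$current_A * 1e9)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "current (nA)")
  if (!is.null(events) && nrow(events) > 0)
    p <- p + ggplot2::geom_point(
      data = events,
      ggplot2::aes(x = .data$peak_time_s,
                   y = (.data$baseline_local_A + .data$peak_amplitude_A) * 1e9),
      colour = "red", shape = 4
    )
  p
}

#' Plot the residual surface of an analyte fit
#'
#' Log-residual heat map over the (radius, valence) grid, with the fitted
#' optimum marked.
#'
#' @param object An `analyte_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot analyte_fit
#' @export
autoplot.analyte_fit <- function(object, ...) {
  s <- object$residual_surface
  ggplot2::ggplot(s, ggplot2::aes(x = .data$r_nm, y = .data$z,
                                  fill = log10(.data$residual + 1e-300))) +
    ggplot2::geom_raster() +
    ggplot2::annotate("point", x = object$r_hat * 1e9, y = object$z_hat,
                      colour = "white", shape = 3) +
    ggplot2::labs(x = "analyte radius (nm)", y = "valence charge z",
                  fill = "log10 residual")
}
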