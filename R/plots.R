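#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a stimulation waveform
#'
#' Current trace with pulse onsets; long waveforms are windowed via
#' `xlim`.
#'
#' @param object A `pac_waveform`.
#' @param xlim Optional `c(t0, t1)` window, s.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot pac_waveform
#' @export
autoplot.pac_waveform <- function(object, xlim = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(xlim))
    df <- dplyr::filter(df, .data$time >= xlim[1], .data$time <= xlim[2])
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$current)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "current (uA)") +
    ggplot2::theme_minimal()
}

#' Plot a scalogram or baseline z-map
#'
#' Heat map of coefficient magnitude (or z) over time and log frequency.
#' The time axis is decimated to at most `max_cols` columns for display.
#'
#' @param object A `pac_scalogram` or `pac_zmap`.
#' @param max_cols Maximum time bins to draw.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot pac_scalogram
#' @export
autoplot.pac_scalogram <- function(object, max_cols = 1000, ...) {
  vals <- Mod(object$coefficients)
  plot_tf_map(vals, object$times, object$freqs, max_cols, "|W|")
}

#' @rdname autoplot.pac_scalogram
#' @method autoplot pac_zmap
#' @export
autoplot.pac_zmap <- function(object, max_cols = 1000, ...) {
  plot_tf_map(object$z, object$times, object$freqs, max_cols, "z")
}

plot_tf_map <- function(vals, times, freqs, max_cols, fill_lab) {
  step <- max(1L, floor(length(times) / max_cols))
  sel <- seq(1L, length(times), by = step)
  df <- tidyr::expand_grid(time = times[sel], freq = freqs)
  df$value <- as.vector(t(vals[sel, , drop = FALSE]))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$freq,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)", fill = fill_lab) +
    ggplot2::theme_minimal()
}

#' Plot a comodulogram
#'
#' Heat map of the modulation index over (phase frequency x amplitude
#' frequency), averaged across sliding windows.
#'
#' @param object A `pac_comodulogram`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot pac_comodulogram
#' @export
autoplot.pac_comodulogram <- function(object, ...) {
  df <- pool_comodulogram(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$f_phase, .data$f_amp,
                                   fill = .data$mi)) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "phase frequency (Hz)",
                  y = "amplitude frequency (Hz)",
                  fill = "MI") +
    ggplot2::theme_minimal()
}

#' Plot a dose-response result
#'
#' Delta-band change (baseline z units) against stimulation amplitude,
#' with the suppression criterion and the detected threshold marked.
#'
#' @param object A `dose_response`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot dose_response
#' @export
autoplot.dose_response <- function(object, ...) {
  df <- object$table
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$amplitude, .data$delta_z)) +
    ggplot2::geom_hline(yintercept = object$criterion, linetype = 2,
                        colour = "red") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$suppressed), size = 2) +
    ggplot2::labs(x = "stimulation amplitude (uA)",
                  y = sprintf("%s-band change (baseline z)",
                              object$band$name)) +
    ggplot2::theme_minimal()
  if (!is.na(object$threshold))
    p <- p + ggplot2::geom_vline(xintercept = object$threshold,
                                 linetype = 3)
  p
}

#' @importFrom rlang .data
NULL
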