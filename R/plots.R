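#' Raster plot of spiking activity
#'
#' @param x a [spike_trains()] object.
#' @param ids sources to show (default all, in order).
#' @param color point color.
#' @return a ggplot.
#' @export
plot_raster <- function(x, ids = NULL, color = "steelblue4") {
  d <- if (is.null(ids)) x else st_subset(x, ids)
  ggplot2::ggplot(as_tibble(d),
                  ggplot2::aes(x = .data$time, y = .data$source)) +
    ggplot2::geom_point(shape = ".", color = color) +
    ggplot2::labs(x = "time (ms)", y = "neuron") +
    ggplot2::theme_minimal()
}

#' PSTH plot
#'
#' @inheritParams psth
#' @return a ggplot.
#' @export
plot_psth <- function(spikes, ids = NULL, binwidth = 5, window = NULL) {
  d <- psth(spikes, ids = ids, binwidth = binwidth, window = window)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$rate)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (ms)", y = "population rate (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a sweep result
#'
#' One-axis sweeps are drawn as SNR (or rate/synchrony) curves; `g_fb` x
#' `g_ff` baseline maps as heat maps.
#'
#' @param object a `striatal_sweep` from [run_sweep()] or
#'   [run_baseline_sweep()].
#' @param y response column to plot (default `"snr"`, or `"rate_msn"` for
#'   baseline maps).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.striatal_sweep <- function(object, y = NULL, ...) {
  d <- as_tibble(object)
  if (all(c("g_fb", "g_ff") %in% names(d)) && !"snr" %in% names(d)) {
    y <- y %||% "rate_msn"
    return(ggplot2::ggplot(d, ggplot2::aes(x = .data$g_ff, y = .data$g_fb,
                                           fill = .data[[y]])) +
             ggplot2::geom_tile() +
             ggplot2::labs(x = "g_FF (nS)", y = "g_FB (nS)", fill = y) +
             ggplot2::theme_minimal())
  }
  y <- y %||% "snr"
  axis <- setdiff(names(d), c("rate_stim", "rate_stim_se", "rate_unstim",
                              "rate_unstim_se", "snr", "sync_stim",
                              "sync_unstim", "n_trials", "rate_msn",
                              "rate_fsi", "sync_msn"))[1]
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[axis]], y = .data[[y]])) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = axis, y = y) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.striatal_sweep
#' @export
autoplot.striatal_competition <- function(object, ...) {
  d <- tidyr::pivot_longer(object$results,
                           cols = c("rate_green", "rate_red"),
                           names_to = "group", values_to = "rate")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$c_red, y = .data$rate,
                                  color = .data$group)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_color_manual(values = c(rate_green = "forestgreen",
                                           rate_red = "firebrick")) +
    ggplot2::labs(x = "red-group within-pool correlation",
                  y = "output rate (Hz)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
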