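#' Plot helpers
#'
#' Lightweight ggplot2 views of the main result types. ggplot2 is a
#' suggested dependency; these raise a clear error when it is unavailable.
#'
#' @name plots
NULL

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("install ggplot2 to use the plot helpers")
}

#' @rdname plots
#' @param x An `lcurve` result from [lcurve_select()] (its `curve` tibble).
#' @return A ggplot object.
#' @export
plot_lcurve <- function(x) {
  .need_ggplot()
  curve <- if (is.list(x) && !is.null(x$curve)) x$curve else x
  ggplot2::ggplot(curve, ggplot2::aes(x = residual_norm,
                                      y = penalty_norm)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(ggplot2::aes(colour = log10(lambda))) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "data residual norm", y = "penalty norm",
                  colour = "log10(lambda)")
}

#' @rdname plots
#' @param res A `residual_spectra` object.
#' @param channels Channel indices to draw (default all).
#' @export
plot_residual_spectra <- function(res, channels = NULL) {
  .need_ggplot()
  tab <- tidy_residuals(res)
  if (!is.null(channels)) tab <- tab[tab$channel %in% channels, ]
  ggplot2::ggplot(tab, ggplot2::aes(x = wavelength_nm, y = diff,
                                    group = channel)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "wavelength (nm)",
                  y = "residual difference r2 - r3 (OD)")
}

#' @rdname plots
#' @param conc A `channel_concentration_series`.
#' @param channel One channel id or index.
#' @export
plot_concentrations <- function(conc, channel = 1) {
  .need_ggplot()
  tab <- tidy_concentrations(conc)
  ch <- if (is.numeric(channel)) conc$channel_ids[channel] else channel
  tab <- tab[tab$channel == ch, ]
  ggplot2::ggplot(tab, ggplot2::aes(x = time_s, y = delta_conc_uM,
                                    colour = chromophore)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "concentration change (uM)",
                  title = paste("channel", ch))
}
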