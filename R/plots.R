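#' Quick-look plot of flash-series transients
#'
#' Draws the time courses at a few wavenumbers (nearest grid points to
#' `wavenumbers`), one facet per flash, log-spaced time axis after the flash.
#'
#' @param object a [flash_series()].
#' @param wavenumbers wavenumbers to show (defaults to three spread across
#'   the grid).
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.flash_series <- function(object, wavenumbers = NULL, ...) {
  wg <- as.numeric(attr(object, "wavenumbers"))
  if (is.null(wavenumbers))
    wavenumbers <- wg[unique(pmax(1, round(c(0.2, 0.5, 0.8) * length(wg))))]
  pick <- vapply(wavenumbers, function(w) wg[which.min(abs(wg - w))], 1)
  d <- dplyr::filter(tibble::as_tibble(object),
                     .data$wavenumber %in% pick, .data$time_us > 0)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_us / 1e3, .data$dod * 1e6,
                                  colour = factor(.data$wavenumber))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~flash, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time after flash (ms)",
                  y = expression(Delta * A ~ (mu * OD)),
                  colour = expression(cm^-1)) +
    ggplot2::theme_minimal()
}

#' Plot the period-four flash pattern of oxygen yields
#'
#' @param params a [kok_params()].
#' @param n_flashes flashes to display.
#' @return A ggplot of [o2_yield_pattern()] with points and a connecting
#'   line, showing the damped period-4 oscillation.
#' @export
plot_o2_pattern <- function(params, n_flashes = 20) {
  d <- o2_yield_pattern(params, n_flashes)
  ggplot2::ggplot(d, ggplot2::aes(.data$flash, .data$yield)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "flash number", y = expression(O[2] ~ yield)) +
    ggplot2::theme_minimal()
}
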