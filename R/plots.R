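#' Plot a spectrum
#'
#' @param object A `raman_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot raman_spectrum
#' @export
autoplot.raman_spectrum <- function(object, ...) {
  lab <- switch(spectrum_representation(object),
    raw = "intensity (counts)",
    reduced = "reduced intensity",
    susceptibility = "Raman susceptibility χ″(ω)"
  )
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$wavenumber, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(omega ~ (cm^-1)), y = lab,
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' Plot a spectral series
#'
#' Spectra are coloured along the series axis.
#'
#' @param object A `raman_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot raman_series
#' @export
autoplot.raman_series <- function(object, ...) {
  axis_name <- if (series_axis(object) == "time") "time (min)" else "temperature (K)"
  vals <- series_axis_values(object)
  long <- purrr::map_dfr(seq_len(nrow(object)), function(i) {
    sp <- object$spectrum[[i]]
    tibble(wavenumber = sp$wavenumber, intensity = sp$intensity,
           axis = vals[i])
  })
  ggplot2::ggplot(long, ggplot2::aes(.data$wavenumber, .data$intensity,
                                     group = .data$axis, colour = .data$axis)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::scale_colour_viridis_c(name = axis_name) +
    ggplot2::labs(x = expression(omega ~ (cm^-1)), y = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot a transformation curve
#'
#' @param object A `transformation_curve`.
#' @param log_time Use a logarithmic time axis.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot transformation_curve
#' @export
autoplot.transformation_curve <- function(object, log_time = FALSE, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(.data$time_min, .data$rho)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(x = "time (min)", y = expression(rho)) +
    ggplot2::theme_minimal()
  if ("water_escape" %in% names(object)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(y = .data$water_escape),
                                 colour = "steelblue", shape = 1)
  }
  if (log_time) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot a kinetic fit
#'
#' Data points with the fitted model curve overlaid.
#'
#' @param object A `kinetic_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kinetic_fit
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  tgrid <- seq(min(object$data$time_min), max(object$data$time_min),
               length.out = 200)
  line <- tibble(
    time_min = tgrid,
    rho = model_rho(object$model, object$k, tgrid,
                    n = if (is.na(object$n)) NULL else object$n)
  )
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time_min, .data$rho)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = line, colour = "firebrick") +
    ggplot2::labs(
      x = "time (min)", y = expression(rho),
      title = sprintf("%s fit: k = %.3g%s, R² = %.4f",
                      object$model, object$k,
                      if (is.na(object$n)) "" else sprintf(", n = %.3f", object$n),
                      object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a spectral decomposition
#'
#' Data, fitted total and the individual components over the fit window.
#'
#' @param object A `decomposition_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot decomposition_fit
#' @export
autoplot.decomposition_fit <- function(object, ...) {
  omega <- object$data$wavenumber
  par_list <- split(object$components$estimate, object$components$component)
  comp_long <- purrr::map_dfr(seq_along(object$template), function(i) {
    comp <- object$template[[i]]
    p <- setNames(par_list[[i]], names(comp$par))
    tibble(wavenumber = omega, intensity = eval_component(comp, omega, p),
           component = sprintf("%d: %s", i, comp$type))
  })
  ggplot2::ggplot(object$data, ggplot2::aes(.data$wavenumber, .data$intensity)) +
    ggplot2::geom_point(size = 0.6, colour = "grey40") +
    ggplot2::geom_line(data = comp_long,
                       ggplot2::aes(colour = .data$component)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), linewidth = 0.8) +
    ggplot2::labs(x = expression(omega ~ (cm^-1)), y = "intensity") +
    ggplot2::theme_minimal()
}
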