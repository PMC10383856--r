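#' Construct a Raman spectrum
#'
#' A spectrum is a tibble with columns `wavenumber` (cm^-1, strictly
#' increasing) and `intensity`, carrying its representation and environment
#' metadata as attributes. Three representations are distinguished: `"raw"`
#' detector counts I(omega, T), Bose-factor `"reduced"` intensity
#' Ir(omega) = I / ((n+1) * omega), and Raman `"susceptibility"`
#' chi''(omega) = omega * Ir(omega).
#'
#' @param wavenumber Numeric vector of Raman shifts in cm^-1, strictly
#'   increasing, length >= 8.
#' @param intensity Numeric vector of intensities, same length.
#' @param representation One of `"raw"`, `"reduced"`, `"susceptibility"`.
#' @param temperature Sample temperature in kelvin (optional for raw spectra;
#'   required before Bose reduction).
#' @param time Elapsed time in minutes (optional).
#' @param rh Relative humidity in percent (optional).
#' @param label Free-text label.
#' @return A `raman_spectrum` tibble.
#' @examples
#' sp <- raman_spectrum(seq(5, 200, 0.5), rep(1, 391), temperature = 298.15)
#' sp
#' @export
raman_spectrum <- function(wavenumber, intensity,
                           representation = "raw",
                           temperature = NULL, time = NULL, rh = NULL,
                           label = NULL) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  representation <- match.arg(representation, .representations)
  if (length(wavenumber) != length(intensity)) {
    abort("`wavenumber` and `intensity` must have the same length.",
          class = "ramankin_degenerate_error")
  }
  if (length(wavenumber) < 8) {
    abort("A spectrum needs at least 8 points.",
          class = "ramankin_degenerate_error")
  }
  if (anyNA(wavenumber) || any(!is.finite(wavenumber))) {
    abort("Wavenumbers must be finite.", class = "ramankin_data_error")
  }
  if (any(diff(wavenumber) <= 0)) {
    abort("Wavenumbers must be strictly increasing.",
          class = "ramankin_data_error")
  }
  out <- tibble(wavenumber = wavenumber, intensity = intensity)
  structure(out,
    class = c("raman_spectrum", class(out)),
    representation = representation,
    temperature = if (is.null(temperature)) NA_real_ else as.numeric(temperature),
    time = if (is.null(time)) NA_real_ else as.numeric(time),
    rh = if (is.null(rh)) NA_real_ else as.numeric(rh),
    label = if (is.null(label)) NA_character_ else as.character(label)
  )
}

#' Spectrum metadata accessors
#'
#' @param x A `raman_spectrum`.
#' @return `spectrum_representation()` returns the representation tag;
#'   `spectrum_meta()` a named list of temperature (K), time (min),
#'   rh (%) and label.
#' @export
spectrum_representation <- function(x) attr(x, "representation")

#' @rdname spectrum_representation
#' @export
spectrum_meta <- function(x) {
  list(
    representation = attr(x, "representation"),
    temperature = attr(x, "temperature"),
    time = attr(x, "time"),
    rh = attr(x, "rh"),
    label = attr(x, "label")
  )
}

# Rebuild a spectrum with new data/metadata, defaulting to the parent's.
spectrum_update <- function(x, wavenumber = NULL, intensity = NULL,
                            representation = NULL, temperature = NULL,
                            time = NULL, rh = NULL, label = NULL) {
  m <- spectrum_meta(x)
  raman_spectrum(
    wavenumber %||% x$wavenumber,
    intensity %||% x$intensity,
    representation = representation %||% m$representation,
    temperature = temperature %||% m$temperature,
    time = time %||% m$time,
    rh = rh %||% m$rh,
    label = label %||% m$label
  )
}

#' @export
print.raman_spectrum <- function(x, ...) {
  m <- spectrum_meta(x)
  cat(sprintf(
    "<raman_spectrum> %d points, %.4g-%.4g cm-1, representation: %s\n",
    nrow(x), min(x$wavenumber), max(x$wavenumber), m$representation
  ))
  if (!is.na(m$temperature)) cat(sprintf("  temperature: %.2f K\n", m$temperature))
  if (!is.na(m$time)) cat(sprintf("  time: %g min\n", m$time))
  if (!is.na(m$rh)) cat(sprintf("  rh: %g %%\n", m$rh))
  if (!is.na(m$label)) cat(sprintf("  label: %s\n", m$label))
  NextMethod()
  invisible(x)
}

stop_if_not_spectrum <- function(x, arg = "spectrum") {
  if (!inherits(x, "raman_spectrum")) {
    abort(sprintf("`%s` must be a raman_spectrum.", arg),
          class = "ramankin_type_error")
  }
  invisible(x)
}
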