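#' Bose thermal occupation factor n(omega, T) + 1
#'
#' The Stokes Raman intensity at low frequency is dominated by the thermal
#' population of the scattering modes. The occupation factor
#' `n + 1 = 1 / (1 - exp(-c2 * omega / T))`, with the second radiation
#' constant c2 = hc/kB = 1.4387769 cm K, removes this trivial temperature
#' dependence when dividing it out. The factor is always > 1, decreases
#' with `omega` and increases with `temperature`.
#'
#' @param omega Raman shift(s) in cm^-1, > 0.
#' @param temperature Temperature(s) in kelvin, > 0.
#' @return Dimensionless factor(s), vectorized over both arguments.
#' @examples
#' bose_factor(20, 298.15) # about 10.87
#' @export
bose_factor <- function(omega, temperature) {
  if (any(omega <= 0)) {
    abort("`omega` must be > 0.", class = "ramankin_domain_error")
  }
  if (any(temperature <= 0)) {
    abort("`temperature` must be > 0 (kelvin).", class = "ramankin_domain_error")
  }
  x <- C2_CM_K * omega / temperature
  1 / (-expm1(-x))
}

#' Laser excitation configuration
#'
#' @param omega0 Absolute excitation wavenumber in cm^-1.
#' @param wavelength_nm Alternatively, the laser wavelength in nm
#'   (omega0 = 1e7 / wavelength_nm; 660 nm gives about 15152 cm^-1).
#' @return A `laser_config` list with element `omega0`.
#' @export
laser_config <- function(omega0 = NULL, wavelength_nm = NULL) {
  if (is.null(omega0)) {
    if (is.null(wavelength_nm)) {
      abort("Give `omega0` or `wavelength_nm`.", class = "ramankin_domain_error")
    }
    omega0 <- 1e7 / wavelength_nm
  }
  if (omega0 <= 0) abort("`omega0` must be > 0.", class = "ramankin_domain_error")
  structure(list(omega0 = omega0), class = "laser_config")
}

#' Bose-factor reduced intensity
#'
#' Transforms raw intensity to reduced intensity
#' `Ir(omega) = I(omega, T) / ((n(omega, T) + 1) * omega)` pointwise.
#' Points below the low-frequency cutoff are dropped: the division by
#' `omega` is handled by the hard cutoff (default 5 cm^-1, the practical
#' detection limit of high-rejection spectrometers), not by regularization.
#'
#' @param x A raw `raman_spectrum`, or a `raman_series` of raw spectra.
#' @param temperature Kelvin; defaults to the spectrum's own metadata.
#' @param cutoff Low-frequency cutoff in cm^-1 (default 5).
#' @return The reduced-intensity spectrum or series.
#' @export
reduce_intensity <- function(x, temperature = NULL, cutoff = 5) {
  UseMethod("reduce_intensity")
}

#' @export
reduce_intensity.raman_spectrum <- function(x, temperature = NULL, cutoff = 5) {
  if (cutoff <= 0) abort("`cutoff` must be > 0.", class = "ramankin_domain_error")
  if (spectrum_representation(x) != "raw") {
    abort("reduce_intensity() expects a raw spectrum.",
          class = "ramankin_representation_error")
  }
  temperature <- temperature %||% attr(x, "temperature")
  if (is.na(temperature)) {
    abort("Temperature (kelvin) is required for Bose reduction.",
          class = "ramankin_metadata_error")
  }
  keep <- x$wavenumber >= cutoff
  if (!any(keep)) {
    abort("All points fall below the cutoff.", class = "ramankin_degenerate_error")
  }
  w <- x$wavenumber[keep]
  ir <- x$intensity[keep] / (bose_factor(w, temperature) * w)
  spectrum_update(x, wavenumber = w, intensity = ir,
                  representation = "reduced", temperature = temperature)
}

#' @export
reduce_intensity.raman_series <- function(x, temperature = NULL, cutoff = 5) {
  spectra <- lapply(x$spectrum, reduce_intensity,
                    temperature = temperature, cutoff = cutoff)
  series_update_spectra(x, spectra)
}

#' Raman susceptibility chi''(omega) = omega * Ir(omega)
#'
#' Converts a reduced-intensity spectrum to Raman susceptibility. Together
#' with [reduce_intensity()] this gives the algebraic identity
#' `chi''(omega) = I(omega, T) / (n(omega, T) + 1)`.
#'
#' @param x A reduced `raman_spectrum`, or a `raman_series` of them.
#' @return The susceptibility spectrum or series.
#' @export
to_susceptibility <- function(x) UseMethod("to_susceptibility")

#' @export
to_susceptibility.raman_spectrum <- function(x) {
  if (spectrum_representation(x) != "reduced") {
    abort("to_susceptibility() expects a reduced spectrum.",
          class = "ramankin_representation_error")
  }
  spectrum_update(x, intensity = x$intensity * x$wavenumber,
                  representation = "susceptibility")
}

#' @export
to_susceptibility.raman_series <- function(x) {
  series_update_spectra(x, lapply(x$spectrum, to_susceptibility))
}

#' Convert a spectrum to reduced representation from any representation
#'
#' Raw spectra are passed through [reduce_intensity()] (temperature
#' required); susceptibility spectra are divided by omega (the exact
#' inverse of [to_susceptibility()]); reduced spectra are returned as-is.
#'
#' @inheritParams reduce_intensity
#' @return A reduced `raman_spectrum` or `raman_series`.
#' @export
as_reduced <- function(x, temperature = NULL, cutoff = 5) UseMethod("as_reduced")

#' @export
as_reduced.raman_spectrum <- function(x, temperature = NULL, cutoff = 5) {
  switch(spectrum_representation(x),
    raw = reduce_intensity(x, temperature = temperature, cutoff = cutoff),
    reduced = x,
    susceptibility = spectrum_update(x, intensity = x$intensity / x$wavenumber,
                                     representation = "reduced")
  )
}

#' @export
as_reduced.raman_series <- function(x, temperature = NULL, cutoff = 5) {
  series_update_spectra(x, lapply(x$spectrum, as_reduced,
                                  temperature = temperature, cutoff = cutoff))
}

#' Optional (omega0 - omega)^4 spectrometer-response correction
#'
#' Raw Stokes intensity is proportional to `(omega0 - omega)^4` through the
#' scattered-light frequency. This correction divides it out, normalized to
#' 1 at omega = 0 so intensity scales stay comparable:
#' intensities are divided by `((omega0 - omega) / omega0)^4`. It is kept
#' separate (and off by default in the pipeline) because the dependence is
#' a proportionality of the raw signal, not a mandated transform.
#'
#' @param spectrum A `raman_spectrum` (any representation; unchanged tag).
#' @param laser A [laser_config()].
#' @param invert Apply the inverse correction (for round trips).
#' @return The corrected spectrum.
#' @export
omega4_correct <- function(spectrum, laser, invert = FALSE) {
  stop_if_not_spectrum(spectrum)
  if (!inherits(laser, "laser_config")) laser <- laser_config(omega0 = laser)
  if (laser$omega0 <= max(spectrum$wavenumber)) {
    abort("`omega0` must exceed the largest analyzed Raman shift.",
          class = "ramankin_domain_error")
  }
  fac <- ((laser$omega0 - spectrum$wavenumber) / laser$omega0)^4
  y <- if (invert) spectrum$intensity * fac else spectrum$intensity / fac
  spectrum_update(spectrum, intensity = y)
}
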