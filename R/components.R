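#' Spectral model components
#'
#' Building blocks for low-frequency spectral decomposition and for the
#' synthetic endmember generator:
#'
#' * `qes_component()`: quasi-elastic scattering, the Stokes half of a
#'   Lorentzian centered at omega = 0:
#'   `L(omega) = amplitude * hwhm^2 / (omega^2 + hwhm^2)`.
#' * `lognormal_vdos()`: vibrational density of states of a disordered
#'   solid, `amplitude * exp(-(ln(omega / center_omega))^2 / (2 * sigma^2))`
#'   (mode at `center_omega`, dimensionless log-width `sigma`; tends to 0
#'   at both omega -> 0+ and omega -> Inf).
#' * `phonon_peak()`: a lattice-mode peak as a pseudo-Voigt with Lorentzian
#'   fraction `eta` in \[0, 1\] (same FWHM for both parts, amplitude =
#'   peak height).
#'
#' Each constructor records initial values and box bounds used by
#' [fit_decomposition()]; the same objects describe synthetic endmembers
#' for [make_endmember()].
#'
#' @param amplitude Peak intensity (>= 0).
#' @param hwhm Lorentzian half width at half maximum, cm^-1 (> 0).
#' @param center_omega Lognormal mode position, cm^-1 (> 0).
#' @param sigma Lognormal log-width (> 0).
#' @param position Peak position, cm^-1.
#' @param fwhm Full width at half maximum, cm^-1 (> 0).
#' @param eta Lorentzian fraction of the pseudo-Voigt, in \[0, 1\].
#' @param lower,upper Optional named numeric vectors overriding the default
#'   box bounds for the component's parameters.
#' @return A `spectral_component` list with fields `type`, `par`, `lower`,
#'   `upper`.
#' @name spectral_components
NULL

new_component <- function(type, par, lower, upper, user_lower, user_upper) {
  if (!is.null(user_lower)) lower[names(user_lower)] <- user_lower
  if (!is.null(user_upper)) upper[names(user_upper)] <- user_upper
  if (any(par < lower - 1e-12) || any(par > upper + 1e-12)) {
    abort(sprintf("Initial %s parameters violate their bounds.", type),
          class = "ramankin_domain_error")
  }
  structure(list(type = type, par = par, lower = lower, upper = upper),
            class = "spectral_component")
}

#' @rdname spectral_components
#' @export
qes_component <- function(amplitude, hwhm, lower = NULL, upper = NULL) {
  new_component(
    "qes",
    c(amplitude = amplitude, hwhm = hwhm),
    c(amplitude = 0, hwhm = 1e-3),
    c(amplitude = Inf, hwhm = Inf),
    lower, upper
  )
}

#' @rdname spectral_components
#' @export
lognormal_vdos <- function(amplitude, center_omega, sigma,
                           lower = NULL, upper = NULL) {
  new_component(
    "lognormal_vdos",
    c(amplitude = amplitude, center_omega = center_omega, sigma = sigma),
    c(amplitude = 0, center_omega = 1e-3, sigma = 1e-3),
    c(amplitude = Inf, center_omega = Inf, sigma = Inf),
    lower, upper
  )
}

#' @rdname spectral_components
#' @export
phonon_peak <- function(position, amplitude, fwhm, eta = 0.5,
                        lower = NULL, upper = NULL) {
  new_component(
    "phonon",
    c(position = position, amplitude = amplitude, fwhm = fwhm, eta = eta),
    c(position = -Inf, amplitude = 0, fwhm = 1e-3, eta = 0),
    c(position = Inf, amplitude = Inf, fwhm = Inf, eta = 1),
    lower, upper
  )
}

# Pointwise evaluation of one component on a wavenumber grid.
eval_component <- function(comp, omega, par = comp$par) {
  switch(comp$type,
    qes = par[["amplitude"]] * par[["hwhm"]]^2 /
      (omega^2 + par[["hwhm"]]^2),
    lognormal_vdos = par[["amplitude"]] *
      exp(-(log(omega / par[["center_omega"]]))^2 / (2 * par[["sigma"]]^2)),
    phonon = {
      g <- par[["fwhm"]] / 2
      lor <- g^2 / ((omega - par[["position"]])^2 + g^2)
      gau <- exp(-log(2) * ((omega - par[["position"]]) / g)^2)
      par[["amplitude"]] * (par[["eta"]] * lor + (1 - par[["eta"]]) * gau)
    },
    abort(sprintf("Unknown component type '%s'.", comp$type),
          class = "ramankin_type_error")
  )
}

eval_template <- function(template, omega, par_list = NULL) {
  total <- numeric(length(omega))
  for (i in seq_along(template)) {
    p <- if (is.null(par_list)) template[[i]]$par else par_list[[i]]
    total <- total + eval_component(template[[i]], omega, p)
  }
  total
}

check_template <- function(template) {
  if (inherits(template, "spectral_component")) template <- list(template)
  if (!length(template)) {
    abort("The component template must contain at least one component.",
          class = "ramankin_spec_error")
  }
  for (comp in template) {
    if (!inherits(comp, "spectral_component")) {
      abort("Template entries must be spectral_component objects.",
            class = "ramankin_type_error")
    }
  }
  template
}
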