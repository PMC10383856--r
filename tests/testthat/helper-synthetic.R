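# Shared builders for small synthetic inputs used across the test files.

default_grid <- function() seq(5, 200, by = 0.5)

# A featureless base form and the same form plus the water-marker band:
# series built from these differ only through the 80 cm-1 band, which is
# the well-posed case for comparing the unmix and band-area estimators.
base_form <- function() {
  endmember(
    phonons = list(phonon_peak(35, 40, 6, eta = 0.5),
                   phonon_peak(120, 25, 9, eta = 0.5)),
    vdos = lognormal_vdos(10, 45, 0.5),
    label = "base form"
  )
}

base_plus_water <- function() {
  endmember(
    phonons = list(phonon_peak(35, 40, 6, eta = 0.5),
                   phonon_peak(80, 50, 25, eta = 0.3),
                   phonon_peak(120, 25, 9, eta = 0.5)),
    vdos = lognormal_vdos(10, 45, 0.5),
    label = "base form + water band"
  )
}

# Exact susceptibility mixtures (1 - rho) * S_h + rho * S_a on a grid,
# with optional homoscedastic Gaussian noise, as a time series.
mixture_series <- function(rho, times = seq_along(rho) * 10,
                           hydrate = base_plus_water(),
                           anhydrate = base_form(),
                           grid = default_grid(),
                           noise_sigma = 0, seed = 1) {
  s_h <- make_endmember(hydrate, grid)
  s_a <- make_endmember(anhydrate, grid)
  chi <- outer(s_h$intensity, 1 - rho) + outer(s_a$intensity, rho)
  if (noise_sigma > 0) {
    chi <- chi + withr::with_seed(
      seed,
      matrix(rnorm(length(chi), sd = noise_sigma * max(s_h$intensity, s_a$intensity)),
             nrow(chi))
    )
  }
  spectra <- lapply(seq_along(rho), function(i) {
    raman_spectrum(grid, chi[, i], representation = "susceptibility",
                   time = times[i])
  })
  list(
    series = raman_series(spectra, axis = "time", axis_values = times),
    ref_hydrate = s_h, ref_anhydrate = s_a
  )
}

# Noiseless transformation curve straight from a kinetic law.
law_curve <- function(model, k, t, n = NULL, method = "generator") {
  transformation_curve(t, model_rho(model, k, t, n = n), method = method)
}

# Same spectrum re-stamped with a time value (for constant series).
with_time <- function(sp, t) {
  raman_spectrum(sp$wavenumber, sp$intensity,
                 representation = spectrum_representation(sp), time = t)
}

# Uniformly rescale every spectrum of a series (metadata preserved).
series_update_spectra_scaled <- function(series, factor) {
  spectra <- lapply(series$spectrum, function(sp) {
    raman_spectrum(sp$wavenumber, sp$intensity * factor,
                   representation = spectrum_representation(sp),
                   time = attr(sp, "time"),
                   temperature = attr(sp, "temperature"))
  })
  raman_series(spectra, axis = series_axis(series),
               axis_values = series_axis_values(series))
}

# g at full conversion for a catalog model (internal registry accessor).
get_kinetic_model_complete <- function(id) {
  ramankin:::get_kinetic_model(id)$g_complete
}
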