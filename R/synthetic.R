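#' Synthetic endmember and simulation specifications
#'
#' `endmember()` describes one crystalline form's low-frequency spectrum
#' as a deterministic sum of phonon peaks, an optional lognormal VDOS and
#' an optional quasi-elastic component (all in susceptibility units).
#' `simulation_spec()` describes a dehydration experiment: the wavenumber
#' grid, the sampling times, the isothermal temperature, the generating
#' kinetic law and the noise level.
#'
#' @param phonons List of [phonon_peak()] components.
#' @param vdos Optional [lognormal_vdos()] component.
#' @param qes Optional [qes_component()].
#' @param label Form label.
#' @return `endmember()` returns an `endmember_spec`;
#'   `simulation_spec()` a `simulation_spec`.
#' @export
endmember <- function(phonons = list(), vdos = NULL, qes = NULL,
                      label = NULL) {
  comps <- c(phonons, if (!is.null(vdos)) list(vdos),
             if (!is.null(qes)) list(qes))
  if (!length(comps)) {
    abort("An endmember needs at least one spectral component.",
          class = "ramankin_spec_error")
  }
  structure(list(components = check_template(comps), label = label),
            class = "endmember_spec")
}

#' @rdname endmember
#' @param grid Wavenumber grid in cm^-1 (default 5-200 at 0.5 steps, the
#'   conventional low-frequency acquisition range).
#' @param times Sampling times in minutes, strictly increasing.
#' @param temperature Isothermal sample temperature, kelvin.
#' @param rh Relative humidity, percent (metadata only).
#' @param model,k,n Generating kinetic law (see [kinetic_models()]).
#' @param noise_sigma Additive Gaussian noise, as a fraction of the
#'   maximum endmember susceptibility; homoscedastic in susceptibility
#'   units.
#' @param seed Integer seed; all randomness flows through it.
#' @export
simulation_spec <- function(times, temperature = 296.15, rh = NULL,
                            model = "avrami", k, n = NULL,
                            noise_sigma = 0.005, seed = 1,
                            grid = seq(5, 200, by = 0.5)) {
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) {
    abort("`times` must be strictly increasing.",
          class = "ramankin_ordering_error")
  }
  if (noise_sigma < 0) {
    abort("`noise_sigma` must be >= 0.", class = "ramankin_domain_error")
  }
  structure(
    list(times = times, temperature = temperature, rh = rh,
         model = model, k = k, n = n,
         noise_sigma = noise_sigma, seed = as.integer(seed), grid = grid),
    class = "simulation_spec"
  )
}

#' Evaluate an endmember spectrum on a grid
#'
#' Deterministic sum of the endmember's component shapes, returned as a
#' susceptibility-representation spectrum.
#'
#' @param spec An [endmember()] specification.
#' @param grid Wavenumber grid, cm^-1.
#' @return A `raman_spectrum` (susceptibility).
#' @export
make_endmember <- function(spec, grid = seq(5, 200, by = 0.5)) {
  if (!inherits(spec, "endmember_spec")) {
    abort("`spec` must be an endmember() specification.",
          class = "ramankin_type_error")
  }
  raman_spectrum(grid, eval_template(spec$components, grid),
                 representation = "susceptibility", label = spec$label)
}

#' Simulate a dehydration spectral series with known ground truth
#'
#' The transformation fraction rho*(t) follows the chosen kinetic law;
#' each spectrum is the susceptibility mixture
#' `(1 - rho*) * S_hydrate + rho* * S_anhydrate` plus additive Gaussian
#' noise (standard deviation `noise_sigma` times the maximum endmember
#' susceptibility), converted to raw intensity through the exact inverse
#' of the Bose reduction: since chi'' = I / (n + 1), raw intensity is
#' `chi'' * (n(omega, T) + 1)`. Running the series back through
#' [reduce_intensity()] and [transformation_rate_unmix()] therefore
#' recovers rho* exactly at zero noise.
#'
#' @param hydrate,anhydrate [endmember()] specifications.
#' @param sim A [simulation_spec()].
#' @return A list with `series` (raw `raman_series`), `truth`
#'   (the generating `transformation_curve`), and the endmember reference
#'   spectra `ref_hydrate`, `ref_anhydrate` (susceptibility).
#' @export
simulate_dehydration <- function(hydrate, anhydrate, sim) {
  if (!inherits(sim, "simulation_spec")) {
    abort("`sim` must be a simulation_spec().", class = "ramankin_type_error")
  }
  s_h <- make_endmember(hydrate, sim$grid)
  s_a <- make_endmember(anhydrate, sim$grid)
  rho_star <- model_rho(sim$model, sim$k, sim$times, n = sim$n)
  chi <- outer(s_h$intensity, 1 - rho_star) +
    outer(s_a$intensity, rho_star)
  scale <- max(s_h$intensity, s_a$intensity)
  noise <- if (sim$noise_sigma > 0) {
    withr::with_seed(sim$seed,
      matrix(rnorm(length(chi), sd = sim$noise_sigma * scale), nrow(chi)))
  } else {
    0
  }
  bose <- bose_factor(sim$grid, sim$temperature)
  raw <- (chi + noise) * bose
  spectra <- lapply(seq_along(sim$times), function(i) {
    raman_spectrum(sim$grid, raw[, i], representation = "raw",
                   temperature = sim$temperature, time = sim$times[i],
                   rh = sim$rh,
                   label = sprintf("simulated t=%g min", sim$times[i]))
  })
  list(
    series = raman_series(spectra, axis = "time", axis_values = sim$times),
    truth = transformation_curve(sim$times, rho_star, method = "generator"),
    ref_hydrate = s_h,
    ref_anhydrate = s_a
  )
}

# log-spaced times from t_half/100 out to 4*t_half, the span needed to
# resolve both kinetic onset and saturation.
logspaced_times <- function(t_half, n = 60) {
  exp(seq(log(t_half / 100), log(4 * t_half), length.out = n))
}

# Endmember tables loosely styled on xanthine-hydrate low-frequency
# features: sharp phonon peaks below 150 cm-1, a broad water-marker band
# near 80 cm-1 present only in the hydrate, an extra 25 cm-1 lattice mode
# in the dehydrated form, and a stronger QES in the disordered product.
theophylline_hydrate_spec <- function() {
  endmember(
    phonons = list(
      phonon_peak(32, 45, 5, eta = 0.5),
      phonon_peak(48, 40, 6, eta = 0.5),
      phonon_peak(80, 60, 28, eta = 0.3),  # water-marker band
      phonon_peak(106, 30, 8, eta = 0.5)
    ),
    vdos = lognormal_vdos(12, 45, 0.55),
    qes = qes_component(12, 8),
    label = "theophylline hydrate (synthetic)"
  )
}

theophylline_anhydrate_spec <- function() {
  endmember(
    phonons = list(
      phonon_peak(25, 30, 5, eta = 0.5),   # extra lattice mode of the product
      phonon_peak(40, 45, 5, eta = 0.5),
      phonon_peak(55, 38, 6, eta = 0.5),
      phonon_peak(115, 30, 8, eta = 0.5),
      phonon_peak(140, 18, 9, eta = 0.5)
    ),
    vdos = lognormal_vdos(8, 40, 0.5),
    qes = qes_component(25, 10),
    label = "theophylline anhydrate (synthetic)"
  )
}

caffeine_hydrate_spec <- function() {
  endmember(
    phonons = list(
      phonon_peak(30, 40, 7, eta = 0.5),
      phonon_peak(52, 35, 9, eta = 0.5),
      phonon_peak(82, 70, 26, eta = 0.3),  # water-marker band
      phonon_peak(112, 25, 10, eta = 0.5)
    ),
    vdos = lognormal_vdos(15, 50, 0.55),
    qes = qes_component(15, 9),
    label = "caffeine hydrate (synthetic)"
  )
}

caffeine_anhydrate_spec <- function() {
  # librational envelope rather than sharp phonons: orientational disorder
  endmember(
    phonons = list(
      phonon_peak(45, 30, 22, eta = 0.6),
      phonon_peak(110, 18, 24, eta = 0.6)
    ),
    vdos = lognormal_vdos(10, 35, 0.6),
    qes = qes_component(35, 12),
    label = "caffeine anhydrate (synthetic)"
  )
}

#' Packaged synthetic dehydration fixtures
#'
#' Ready-made endmember and simulation specifications emulating three
#' study conditions:
#'
#' * `"tp_noRH"`: theophylline-style dehydration without humidity control;
#'   Avrami law with exponent n = 2.95 (nucleation and two-dimensional
#'   growth), t_1/2 = 100 min, noise seed 42.
#' * `"tp_1RH_23C"`: theophylline-style dehydration at 23 C and 1% RH;
#'   Jander three-dimensional diffusion law, t_1/2 = 600 min, seed 44.
#' * `"caf_20RH"`: caffeine-style dehydration at 23 C and 20% RH; Avrami
#'   law with n = 1.410 (nucleation with quasi-absent growth),
#'   t_1/2 = 200 min, seed 43.
#'
#' Rate constants are set from the half-transformation times (Avrami:
#' k = ln 2 / t_1/2^n; Jander: k = g(1/2) / t_1/2); the t_1/2 values are
#' desk-scale conveniences, only the exponents and mechanisms are anchored
#' to reported dehydration kinetics. All fixtures use 60 log-spaced time
#' points out to 4 t_1/2 and noise sigma = 0.005.
#'
#' @param name One of `"tp_noRH"`, `"tp_1RH_23C"`, `"caf_20RH"`.
#' @return A list with `name`, `hydrate`, `anhydrate` (endmember specs)
#'   and `sim` (a [simulation_spec()]).
#' @export
fixture <- function(name) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% c("tp_noRH", "tp_1RH_23C", "caf_20RH")) {
    abort("Unknown fixture; use 'tp_noRH', 'tp_1RH_23C' or 'caf_20RH'.",
          class = "ramankin_lookup_error")
  }
  switch(name,
    tp_noRH = {
      t_half <- 100
      n <- 2.95
      list(
        name = name,
        hydrate = theophylline_hydrate_spec(),
        anhydrate = theophylline_anhydrate_spec(),
        sim = simulation_spec(
          times = logspaced_times(t_half), temperature = 313.15, rh = NULL,
          model = "avrami", k = log(2) / t_half^n, n = n,
          noise_sigma = 0.005, seed = 42
        )
      )
    },
    tp_1RH_23C = {
      t_half <- 600
      list(
        name = name,
        hydrate = theophylline_hydrate_spec(),
        anhydrate = theophylline_anhydrate_spec(),
        sim = simulation_spec(
          times = logspaced_times(t_half), temperature = 296.15, rh = 1,
          model = "D3", k = model_g("D3", 0.5) / t_half,
          noise_sigma = 0.005, seed = 44
        )
      )
    },
    caf_20RH = {
      t_half <- 200
      n <- 1.410
      list(
        name = name,
        hydrate = caffeine_hydrate_spec(),
        anhydrate = caffeine_anhydrate_spec(),
        sim = simulation_spec(
          times = logspaced_times(t_half), temperature = 296.15, rh = 20,
          model = "avrami", k = log(2) / t_half^n, n = n,
          noise_sigma = 0.005, seed = 43
        )
      )
    }
  )
}
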