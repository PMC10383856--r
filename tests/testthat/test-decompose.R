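# Ground-truth QES + lognormal pair used in several blocks.
qes_true <- list(amplitude = 120, hwhm = 11)
vdos_true <- list(amplitude = 60, center = 55, sigma = 0.5)

qes_vdos_spectrum <- function(noise_sigma = 0, seed = 1,
                              grid = seq(5, 150, 0.5)) {
  y <- qes_true$amplitude * qes_true$hwhm^2 / (grid^2 + qes_true$hwhm^2) +
    vdos_true$amplitude *
      exp(-(log(grid / vdos_true$center))^2 / (2 * vdos_true$sigma^2))
  if (noise_sigma > 0) {
    y <- y + withr::with_seed(seed, rnorm(length(grid),
                                          sd = noise_sigma * max(y)))
  }
  raman_spectrum(grid, y, representation = "susceptibility")
}

start_template <- function() {
  list(qes_component(90, 15), lognormal_vdos(40, 70, 0.7))
}

test_that("noiseless QES + lognormal parameters are recovered to 1e-6", {
  fit <- fit_decomposition(qes_vdos_spectrum(), start_template())
  expect_true(fit$converged)
  est <- setNames(fit$components$estimate, fit$components$term)
  truth <- c(qes_true$amplitude, qes_true$hwhm, vdos_true$amplitude,
             vdos_true$center, vdos_true$sigma)
  expect_equal(unname(est), truth, tolerance = 1e-6)
  expect_lt(fit$residual_rms, 1e-8 * max(qes_vdos_spectrum()$intensity))
  # I_QES equals the analytic Lorentzian window area at the estimates
  a <- est[["amplitude"]][1]; g <- est[["hwhm"]][1]
  expect_equal(fit$i_qes, a * g * (atan(150 / g) - atan(5 / g)),
               tolerance = 1e-12)
})

test_that("a redundant lognormal collapses to its zero lower bound", {
  grid <- seq(5, 150, 0.5)
  pure <- raman_spectrum(
    grid, qes_true$amplitude * qes_true$hwhm^2 / (grid^2 + qes_true$hwhm^2),
    representation = "susceptibility"
  )
  fit <- fit_decomposition(pure, list(qes_component(90, 15),
                                      lognormal_vdos(20, 70, 0.7)))
  est <- fit$components
  expect_equal(est$estimate[est$type == "qes" & est$term == "amplitude"],
               qes_true$amplitude, tolerance = 1e-6)
  expect_lt(est$estimate[est$type == "lognormal_vdos" &
                           est$term == "amplitude"],
            1e-6 * qes_true$amplitude)
})

test_that("1% noise leaves parameters within 5% in at least 95 of 100 seeds", {
  truth <- c(qes_true$amplitude, qes_true$hwhm, vdos_true$amplitude,
             vdos_true$center, vdos_true$sigma)
  ok <- 0L
  for (s in 1:100) {
    fit <- fit_decomposition(qes_vdos_spectrum(noise_sigma = 0.01, seed = s),
                             start_template())
    est <- fit$components$estimate
    if (all(abs(est - truth) / truth < 0.05)) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("noisier spectra do not report smaller standard errors", {
  se_at <- function(sig) {
    mean(vapply(1:20, function(s) {
      fit <- fit_decomposition(qes_vdos_spectrum(noise_sigma = sig, seed = s),
                               start_template())
      fit$components$std.error[1]
    }, numeric(1)))
  }
  expect_gt(se_at(0.02), se_at(0.005))
})

test_that("I_QES scales with uniform rescaling and stays non-negative", {
  sp <- qes_vdos_spectrum(noise_sigma = 0.01, seed = 7)
  f1 <- fit_decomposition(sp, start_template())
  sp3 <- raman_spectrum(sp$wavenumber, 3 * sp$intensity,
                        representation = "susceptibility")
  tmpl3 <- list(qes_component(3 * 90, 15), lognormal_vdos(3 * 40, 70, 0.7))
  f3 <- fit_decomposition(sp3, tmpl3)
  expect_gte(f1$i_qes, 0)
  expect_equal(f3$i_qes, 3 * f1$i_qes, tolerance = 1e-6)
})

test_that("phonon peaks fit as pseudo-Voigt with bounded eta", {
  grid <- seq(5, 150, 0.5)
  pk <- phonon_peak(60, 40, 8, eta = 0.3)
  sp <- raman_spectrum(grid, ramankin:::eval_component(pk, grid),
                       representation = "susceptibility")
  fit <- fit_decomposition(sp, list(phonon_peak(55, 30, 12, eta = 0.6)))
  est <- setNames(fit$components$estimate, fit$components$term)
  expect_equal(unname(est[c("position", "amplitude", "fwhm", "eta")]),
               c(60, 40, 8, 0.3), tolerance = 1e-6)
})

test_that("decomposition validates window, representation and data", {
  sp <- qes_vdos_spectrum()
  expect_error(fit_decomposition(sp, start_template(), window = c(300, 400)),
               class = "ramankin_domain_error")
  raw <- raman_spectrum(sp$wavenumber, sp$intensity)
  expect_error(fit_decomposition(raw, start_template()),
               class = "ramankin_representation_error")
  bad <- raman_spectrum(sp$wavenumber, replace(sp$intensity, 10, NaN),
                        representation = "susceptibility")
  expect_error(fit_decomposition(bad, start_template()),
               class = "ramankin_data_error")
  expect_error(fit_decomposition(sp, list()), class = "ramankin_spec_error")
})

test_that("qes_trace is constant on identical spectra and tracks a ramp", {
  sp <- qes_vdos_spectrum()
  const <- raman_series(
    lapply(1:5, function(i) with_time(sp, i * 10)),
    axis = "time"
  )
  tr <- qes_trace(const, start_template())
  expect_true(all(tr$converged))
  expect_lt(diff(range(tr$i_qes)) / mean(tr$i_qes), 1e-8)

  # QES amplitude growing linearly along a temperature ramp
  grid <- seq(5, 150, 0.5)
  temps <- seq(280, 320, 5)
  slope_a <- 2 # amplitude units per kelvin
  spectra <- lapply(temps, function(T) {
    a <- 20 + slope_a * (T - 280)
    y <- a * 10^2 / (grid^2 + 10^2) +
      vdos_true$amplitude *
        exp(-(log(grid / vdos_true$center))^2 / (2 * vdos_true$sigma^2))
    raman_spectrum(grid, y, representation = "susceptibility",
                   temperature = T)
  })
  ramp <- raman_series(spectra, axis = "temperature")
  tr2 <- qes_trace(ramp, list(qes_component(30, 14),
                              lognormal_vdos(40, 70, 0.7)))
  # i_qes = a * 10 * (atan(150/10) - atan(5/10)) so the trace slope is
  # slope_a times that geometric factor
  geom <- 10 * (atan(15) - atan(0.5))
  fit <- lm(i_qes ~ temperature_K, data = tr2)
  expect_equal(unname(coef(fit)[2]), slope_a * geom, tolerance = 0.05)

  # two-phase ramp: step in QES amplitude located within one sample
  step_at <- 300
  spectra3 <- lapply(temps, function(T) {
    a <- if (T < step_at) 30 else 90
    y <- a * 10^2 / (grid^2 + 10^2) +
      vdos_true$amplitude *
        exp(-(log(grid / vdos_true$center))^2 / (2 * vdos_true$sigma^2))
    raman_spectrum(grid, y, representation = "susceptibility",
                   temperature = T)
  })
  tr3 <- qes_trace(raman_series(spectra3, axis = "temperature"),
                   list(qes_component(30, 14), lognormal_vdos(40, 70, 0.7)))
  jump <- which.max(diff(tr3$i_qes))
  expect_lte(abs(tr3$temperature_K[jump + 1] - step_at), 5)
})
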