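test_that("bose_factor matches direct evaluation and limits", {
  # closed form at x = c2 * omega / T = 1: 1 / (1 - e^-1) ~ 1.581977
  expect_equal(bose_factor(200, 1.4387769 * 200), 1 / (1 - exp(-1)),
               tolerance = 1e-12)
  expect_equal(bose_factor(200, 1.4387769 * 200), 1.581977,
               tolerance = 1e-6)
  expect_equal(bose_factor(20, 298.15), 10.870, tolerance = 1e-4)

  # high-frequency limit -> 1
  expect_equal(bose_factor(1e6, 300), 1, tolerance = 1e-12)

  # direct-formula oracle on a 100 x 10 grid, 1e-10 relative
  omega <- seq(5, 200, length.out = 100)
  temps <- seq(200, 350, length.out = 10)
  for (T in temps) {
    direct <- 1 / (1 - exp(-1.4387769 * omega / T))
    expect_equal(bose_factor(omega, T), direct, tolerance = 1e-10)
  }

  # monotone: decreasing in omega, increasing in T; always > 1
  f <- bose_factor(seq(5, 200, 5), 300)
  expect_true(all(diff(f) < 0) && all(f > 1))
  ft <- bose_factor(20, seq(200, 350, 10))
  expect_true(all(diff(ft) > 0))

  expect_error(bose_factor(-1, 300), class = "ramankin_domain_error")
  expect_error(bose_factor(10, 0), class = "ramankin_domain_error")
})

test_that("reduce_intensity inverts its own construction and round-trips", {
  grid <- seq(5, 200, 0.5)
  T <- 298.15
  # raw built as (n+1) * omega reduces to exactly 1
  raw <- raman_spectrum(grid, bose_factor(grid, T) * grid, temperature = T)
  red <- reduce_intensity(raw)
  expect_identical(spectrum_representation(red), "reduced")
  expect_equal(red$intensity, rep(1, length(grid)), tolerance = 1e-12)

  # reduce then multiply back: original raw values to 1e-12 relative
  raw2 <- raman_spectrum(grid, 100 + sin(grid), temperature = T)
  red2 <- reduce_intensity(raw2)
  back <- red2$intensity * bose_factor(red2$wavenumber, T) * red2$wavenumber
  expect_equal(back, raw2$intensity, tolerance = 1e-12)

  # single-point check composed with the bose_factor oracle
  one <- raman_spectrum(c(30, seq(40, 100, 10)), c(100, rep(1, 7)),
                        temperature = T)
  r1 <- reduce_intensity(one)
  expect_equal(r1$intensity[1], 100 / (bose_factor(30, T) * 30),
               tolerance = 1e-14)
})

test_that("reduction enforces cutoff, temperature and representation", {
  grid <- seq(1, 20, 0.5)
  sp <- raman_spectrum(grid, rep(1, length(grid)), temperature = 300)
  red <- reduce_intensity(sp)
  expect_gte(min(red$wavenumber), 5)

  no_t <- raman_spectrum(grid, rep(1, length(grid)))
  expect_error(reduce_intensity(no_t), class = "ramankin_metadata_error")
  expect_error(reduce_intensity(sp, cutoff = 100),
               class = "ramankin_degenerate_error")
  expect_error(reduce_intensity(reduce_intensity(sp)),
               class = "ramankin_representation_error")
})

test_that("susceptibility is omega * Ir and composes to I / (n+1)", {
  grid <- seq(5, 150, 0.5)
  red <- raman_spectrum(grid, rep(2, length(grid)),
                        representation = "reduced", temperature = 300)
  chi <- to_susceptibility(red)
  expect_identical(spectrum_representation(chi), "susceptibility")
  expect_identical(chi$intensity, 2 * grid)
  expect_identical(chi$intensity[grid == 50], 100)

  zero <- raman_spectrum(grid, rep(0, length(grid)),
                         representation = "reduced")
  expect_identical(to_susceptibility(zero)$intensity, rep(0, length(grid)))

  # chi'' = I / (n+1) for any raw input (identity of the two transforms)
  T <- 310
  raw <- raman_spectrum(grid, grid^2 + 3, temperature = T)
  chi2 <- to_susceptibility(reduce_intensity(raw))
  expect_equal(chi2$intensity, raw$intensity / bose_factor(grid, T),
               tolerance = 1e-14)

  expect_error(to_susceptibility(raw), class = "ramankin_representation_error")
  # as_reduced inverts to_susceptibility exactly
  expect_equal(as_reduced(chi)$intensity, red$intensity, tolerance = 1e-15)
})

test_that("omega4 correction normalizes at zero shift and round-trips", {
  laser <- laser_config(omega0 = 15152)
  grid <- seq(5, 150, 0.5)
  sp <- raman_spectrum(grid, rep(1, length(grid)))
  corr <- omega4_correct(sp, laser)
  # at omega -> 0 the correction tends to 1
  expect_equal(corr$intensity[1], 1 / ((15152 - 5) / 15152)^4,
               tolerance = 1e-12)
  expect_equal(corr$intensity[grid == 150], (15152 / 15002)^4,
               tolerance = 1e-12)
  expect_equal(corr$intensity[grid == 150], 1.0406, tolerance = 1e-4)

  # correction then inverse restores the input; twice is not once
  twice <- omega4_correct(corr, laser)
  expect_gt(max(abs(twice$intensity - corr$intensity)), 0)
  back <- omega4_correct(corr, laser, invert = TRUE)
  expect_equal(back$intensity, sp$intensity, tolerance = 1e-12)

  expect_error(omega4_correct(sp, laser_config(omega0 = 100)),
               class = "ramankin_domain_error")
  # 660 nm laser wavelength resolves to ~15152 cm^-1
  expect_equal(laser_config(wavelength_nm = 660)$omega0, 15151.515,
               tolerance = 1e-6)
})

test_that("transforms are pointwise and rescale-equivariant", {
  grid <- seq(5, 150, 1.5)
  y <- 50 + 10 * cos(grid / 7)
  T <- 296.15
  raw <- raman_spectrum(grid, y, temperature = T)
  red <- reduce_intensity(raw)
  # pointwise: each output depends only on its own (omega, I) pair
  sub <- raman_spectrum(grid[seq(1, length(grid), 2)],
                        y[seq(1, length(grid), 2)], temperature = T)
  red_sub <- reduce_intensity(sub)
  expect_equal(red_sub$intensity,
               red$intensity[seq(1, length(grid), 2)], tolerance = 1e-15)
  # linear in intensity
  scaled <- reduce_intensity(raman_spectrum(grid, 3 * y, temperature = T))
  expect_equal(scaled$intensity, 3 * red$intensity, tolerance = 1e-14)
})
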