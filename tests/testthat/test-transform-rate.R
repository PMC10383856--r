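test_that("unmixing recovers exact mixtures and endmembers", {
  rho_star <- c(0, 0.1, 0.35, 0.5, 0.72, 0.9, 1)
  mix <- mixture_series(rho_star)
  cv <- transformation_rate_unmix(mix$series, mix$ref_hydrate,
                                  mix$ref_anhydrate)
  expect_s3_class(cv, "transformation_curve")
  expect_equal(cv$rho, rho_star, tolerance = 1e-10)

  pure_h <- mixture_series(rep(0, 4))
  expect_equal(
    transformation_rate_unmix(pure_h$series, pure_h$ref_hydrate,
                              pure_h$ref_anhydrate)$rho,
    rep(0, 4), tolerance = 1e-12
  )
  pure_a <- mixture_series(rep(1, 4))
  expect_equal(
    transformation_rate_unmix(pure_a$series, pure_a$ref_hydrate,
                              pure_a$ref_anhydrate)$rho,
    rep(1, 4), tolerance = 1e-12
  )
})

test_that("unmixing under 1% noise keeps RMSE(rho) below 0.02", {
  rho_star <- model_rho("avrami", log(2) / 100^2, seq(20, 240, 20), n = 2)
  sq_err <- 0
  n_tot <- 0
  for (s in 1:100) {
    mix <- mixture_series(rho_star, noise_sigma = 0.01, seed = s)
    cv <- transformation_rate_unmix(mix$series, mix$ref_hydrate,
                                    mix$ref_anhydrate)
    sq_err <- sq_err + sum((cv$rho - rho_star)^2)
    n_tot <- n_tot + length(rho_star)
  }
  expect_lt(sqrt(sq_err / n_tot), 0.02)
})

test_that("rho is invariant under uniform intensity rescaling", {
  rho_star <- c(0.05, 0.3, 0.6, 0.92)
  mix <- mixture_series(rho_star, noise_sigma = 0.01, seed = 3)
  cv1 <- transformation_rate_unmix(mix$series, mix$ref_hydrate,
                                   mix$ref_anhydrate)
  scaled <- series_update_spectra_scaled(mix$series, 7.5)
  cv2 <- transformation_rate_unmix(scaled, mix$ref_hydrate,
                                   mix$ref_anhydrate)
  expect_equal(cv2$rho, cv1$rho, tolerance = 1e-9)
  cv3 <- transformation_rate_band(scaled)
  cv4 <- transformation_rate_band(mix$series)
  expect_equal(cv3$rho, cv4$rho, tolerance = 1e-12)
})

test_that("band-area tracking anchors to the endpoints and tracks a law", {
  # linearly decaying band area -> linear rho from 0 to 1
  rho_star <- seq(0, 1, length.out = 9)
  mix <- mixture_series(rho_star)
  cv <- transformation_rate_band(mix$series)
  expect_equal(cv$rho[1], 0)
  expect_equal(cv$rho[length(cv$rho)], 1)
  expect_equal(cv$rho, rho_star, tolerance = 1e-10)
  expect_equal(cv$water_escape, 1 - rho_star, tolerance = 1e-10)

  # Avrami-driven band decay follows the generating law up to noise
  t <- seq(10, 400, 10)
  rho_av <- model_rho("avrami", log(2) / 100^1.5, t, n = 1.5)
  noisy <- mixture_series(rho_av, times = t, noise_sigma = 0.005, seed = 11)
  cvn <- transformation_rate_band(noisy$series)
  expect_lt(max(abs(cvn$rho - rho_av)), 0.05)
})

test_that("band method needs contrast; unmix rejects grid mismatches", {
  flat <- mixture_series(rep(0.4, 5))
  expect_error(transformation_rate_band(flat$series),
               class = "ramankin_no_contrast_error")
  mix <- mixture_series(c(0, 0.5, 1))
  off_grid <- make_endmember(base_plus_water(), seq(6, 199, 0.5))
  expect_error(
    transformation_rate_unmix(mix$series, off_grid, mix$ref_anhydrate),
    class = "ramankin_grid_error"
  )
})

test_that("unmix and band estimators agree when only the water band differs", {
  t <- seq(10, 400, 10)
  rho_star <- model_rho("avrami", log(2) / 120^2, t, n = 2)
  mix <- mixture_series(rho_star, times = t, noise_sigma = 0.005, seed = 5)
  cv_u <- transformation_rate_unmix(mix$series, mix$ref_hydrate,
                                    mix$ref_anhydrate)
  cv_b <- transformation_rate_band(mix$series)
  expect_lt(sqrt(mean((cv_u$rho - cv_b$rho)^2)), 0.02)
})

test_that("monotone generating laws give monotone estimates up to noise", {
  t <- seq(5, 300, 5)
  rho_star <- model_rho("avrami", log(2) / 100^2, t, n = 2)
  dev <- vapply(1:20, function(s) {
    mix <- mixture_series(rho_star, times = t, noise_sigma = 0.01, seed = s)
    cv <- transformation_rate_unmix(mix$series, mix$ref_hydrate,
                                    mix$ref_anhydrate)
    iso <- isoreg(cv$time_min, cv$rho)
    mean(abs(iso$yf - cv$rho))
  }, numeric(1))
  expect_lt(mean(dev), 0.01)
})

test_that("half_time interpolates the first upward crossing", {
  cv <- transformation_curve(c(10, 20), c(0.4, 0.6))
  expect_equal(half_time(cv), 15)
  expect_equal(half_time(transformation_curve(c(3, 7, 9), c(0.1, 0.5, 0.9))), 7)
  # Avrami closed form: t_1/2 = (ln 2 / k)^(1/n)
  k <- 2e-4; n <- 1.7
  t <- seq(1, 800, 1)
  cv_av <- law_curve("avrami", k, t, n = n)
  expect_equal(half_time(cv_av), (log(2) / k)^(1 / n), tolerance = 1e-3)
  expect_error(half_time(transformation_curve(1:6 * 10, rep(0.2, 6))),
               class = "ramankin_incomplete_transformation_error")
})

test_that("master curves collapse over k and separate over n", {
  n <- 2.2
  k1 <- 5e-5
  t1 <- exp(seq(log(2), log(4000), length.out = 80))
  m1 <- master_curve(law_curve("avrami", k1, t1, n = n))
  # k x10 with the time grid scaled accordingly samples identical rho
  s <- (1 / 10)^(1 / n)
  m2 <- master_curve(law_curve("avrami", 10 * k1, t1 * s, n = n))
  expect_lt(max(abs(m1$rho - m2$rho)), 1e-10)
  expect_lt(max(abs(m1$time_min - m2$time_min)), 1e-10)

  # interpolated value at t/t_half = 1 is 0.5
  expect_equal(approx(m1$time_min, m1$rho, xout = 1)$y, 0.5,
               tolerance = 1e-6)

  # different exponents give different master curves
  t <- seq(1, 400, 1)
  mA <- master_curve(law_curve("avrami", log(2) / 100, t, n = 1))
  mB <- master_curve(law_curve("avrami", log(2) / 100^3, t, n = 3))
  common <- seq(0.3, 2, 0.01)
  dA <- approx(mA$time_min, mA$rho, xout = common)$y
  dB <- approx(mB$time_min, mB$rho, xout = common)$y
  expect_gt(max(abs(dA - dB)), 0.1)
})
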