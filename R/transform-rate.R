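#' Transformation-rate curves
#'
#' A transformation curve is a tibble with strictly increasing `time_min`
#' and the transformation fraction `rho` in \[0, 1\] (hydrate -> anhydrate
#' conversion), optionally with a normalized `water_escape` trace. It is
#' produced by [transformation_rate_unmix()], [transformation_rate_band()]
#' or directly from a kinetic law, and consumed by [fit_kinetics()],
#' [half_time()] and [master_curve()].
#'
#' @param time_min Strictly increasing times, minutes.
#' @param rho Transformation fraction; clipped into \[0, 1\].
#' @param water_escape Optional normalized water-band trace in \[0, 1\].
#' @param method Estimator tag (`"unmix"`, `"band"`, `"generator"`).
#' @return A `transformation_curve` tibble.
#' @export
transformation_curve <- function(time_min, rho, water_escape = NULL,
                                 method = "unmix") {
  time_min <- as.numeric(time_min)
  rho <- as.numeric(rho)
  if (length(time_min) != length(rho)) {
    abort("`time_min` and `rho` must have the same length.",
          class = "ramankin_degenerate_error")
  }
  if (any(diff(time_min) <= 0)) {
    abort("`time_min` must be strictly increasing.",
          class = "ramankin_ordering_error")
  }
  out <- tibble(time_min = time_min, rho = pmin(pmax(rho, 0), 1))
  if (!is.null(water_escape)) out$water_escape <- as.numeric(water_escape)
  structure(out, class = c("transformation_curve", class(out)),
            method = method)
}

as_transformation_curve <- function(curve) {
  if (inherits(curve, "transformation_curve")) return(curve)
  if (is.data.frame(curve) && all(c("time_min", "rho") %in% names(curve))) {
    return(transformation_curve(curve$time_min, curve$rho,
                                water_escape = curve[["water_escape"]],
                                method = attr(curve, "method") %||% "unmix"))
  }
  abort("Expected a transformation_curve or a data frame with `time_min` and `rho`.",
        class = "ramankin_type_error")
}

#' Transformation rate by two-endmember non-negative unmixing
#'
#' Each spectrum of the series is modelled as a non-negative combination
#' `I_t ~ a * S_hydrate + b * S_anhydrate` (constrained least squares,
#' a, b >= 0) and the transformation fraction is the abundance ratio
#' `rho = b / (a + b)`. Closure a + b = 1 is deliberately not imposed:
#' overall scattering efficiency may drift during dehydration, and the
#' ratio is invariant under any uniform intensity rescaling. Unmixing is
#' normally run on reduced-intensity spectra so the trivial Bose
#' temperature dependence is already removed.
#'
#' This estimator (and the water-band variant) is this package's explicit
#' choice of rho estimator for dehydration series; it is not a published
#' reference algorithm.
#'
#' @param series A `raman_series`, same representation and grid as the
#'   references.
#' @param ref_hydrate,ref_anhydrate Endmember `raman_spectrum` references.
#' @return A `transformation_curve` (method `"unmix"`).
#' @export
transformation_rate_unmix <- function(series, ref_hydrate, ref_anhydrate) {
  stop_if_not_series(series)
  stop_if_not_spectrum(ref_hydrate, "ref_hydrate")
  stop_if_not_spectrum(ref_anhydrate, "ref_anhydrate")
  grid <- series_grid(series)
  for (ref in list(ref_hydrate, ref_anhydrate)) {
    if (length(ref$wavenumber) != length(grid) || !all(ref$wavenumber == grid)) {
      abort("References and series must share one wavenumber grid; resample first.",
            class = "ramankin_grid_error")
    }
  }
  reps <- unique(c(series_representation(series),
                   spectrum_representation(ref_hydrate),
                   spectrum_representation(ref_anhydrate)))
  if (length(reps) != 1) {
    abort("Series and references must share one representation.",
          class = "ramankin_representation_error")
  }
  A <- cbind(hydrate = ref_hydrate$intensity,
             anhydrate = ref_anhydrate$intensity)
  rho <- vapply(series$spectrum, function(sp) {
    ab <- pracma::lsqnonneg(A, sp$intensity)$x
    if (sum(ab) <= 0) {
      abort("Zero spectrum: both endmember abundances vanish.",
            class = "ramankin_degenerate_error")
    }
    ab[2] / sum(ab)
  }, numeric(1))
  if (series_axis(series) != "time") {
    abort("Transformation curves need a time-axis series.",
          class = "ramankin_ordering_error")
  }
  transformation_curve(series$time_min, rho, method = "unmix")
}

#' Transformation rate by water-band area tracking
#'
#' Tracks the trapezoidal area `A(t)` of the hydrate water-marker band
#' (default window 60-100 cm^-1, bracketing the band near 80 cm^-1 that is
#' present only while structural water remains) and anchors the
#' transformation fraction to the first and last spectra:
#' `rho(t) = (A0 - A(t)) / (A0 - Ainf)`. The `water_escape` column is the
#' complementary normalized band area `(A(t) - Ainf) / (A0 - Ainf)`, i.e.
#' the fraction of the water signal still present.
#'
#' @param series A time-axis `raman_series`.
#' @param band_window Integration window `c(lo, hi)` in cm^-1 (default
#'   `c(60, 100)`).
#' @return A `transformation_curve` (method `"band"`) with `water_escape`.
#' @export
transformation_rate_band <- function(series, band_window = c(60, 100)) {
  stop_if_not_series(series)
  if (series_axis(series) != "time") {
    abort("Transformation curves need a time-axis series.",
          class = "ramankin_ordering_error")
  }
  grid <- series_grid(series)
  keep <- grid >= band_window[1] & grid <= band_window[2]
  if (sum(keep) < 2) {
    abort("The band window must contain at least two grid points.",
          class = "ramankin_domain_error")
  }
  area <- vapply(series$spectrum, function(sp) {
    pracma::trapz(grid[keep], sp$intensity[keep])
  }, numeric(1))
  a0 <- area[1]
  ainf <- area[length(area)]
  if (a0 == ainf) {
    abort("No band-area contrast between the first and last spectra.",
          class = "ramankin_no_contrast_error")
  }
  escape <- (area - ainf) / (a0 - ainf)
  transformation_curve(series$time_min, (a0 - area) / (a0 - ainf),
                       water_escape = pmin(pmax(escape, 0), 1),
                       method = "band")
}

#' Time to half-transformation
#'
#' Linear interpolation between the samples bracketing the first upward
#' crossing of rho = 0.5 (a sample exactly at 0.5 counts as the crossing).
#' The first-crossing rule keeps t_1/2 deterministic under noise.
#'
#' @param curve A `transformation_curve` (or data frame with `time_min`,
#'   `rho`).
#' @return t_1/2 in minutes.
#' @export
half_time <- function(curve) {
  curve <- as_transformation_curve(curve)
  t <- curve$time_min
  r <- curve$rho
  for (i in seq_along(r)) {
    if (r[i] == 0.5) return(t[i])
    if (i > 1 && r[i - 1] < 0.5 && r[i] > 0.5) {
      return(t[i - 1] + (0.5 - r[i - 1]) / (r[i] - r[i - 1]) * (t[i] - t[i - 1]))
    }
  }
  abort("rho never crosses 0.5: transformation incomplete.",
        class = "ramankin_incomplete_transformation_error")
}

#' Master curve: rescale time by the half-transformation time
#'
#' Replaces the time axis by t / t_1/2, leaving rho unchanged. Curves
#' sharing one kinetic mechanism collapse onto a single master curve in
#' this representation regardless of their rate constants (for the Avrami
#' law, rho = 1 - exp(-ln 2 * (t / t_1/2)^n) depends on n only).
#'
#' @inheritParams half_time
#' @return A `transformation_curve` whose `time_min` column holds t/t_1/2
#'   (dimensionless); the t_1/2 used is stored in attribute `t_half`.
#' @export
master_curve <- function(curve) {
  curve <- as_transformation_curve(curve)
  th <- half_time(curve)
  out <- transformation_curve(curve$time_min / th, curve$rho,
                              water_escape = curve[["water_escape"]],
                              method = attr(curve, "method"))
  attr(out, "t_half") <- th
  out
}
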