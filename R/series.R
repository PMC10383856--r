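#' Construct an ordered spectral series
#'
#' A series is a tibble with one row per spectrum and a `spectrum`
#' list-column, ordered along a strictly increasing time or temperature
#' axis. All spectra must share an identical wavenumber grid; resampling is
#' an explicit operation ([resample_common_grid()]), never implicit.
#'
#' @param spectra List of `raman_spectrum` objects, all on one grid.
#' @param axis `"time"` or `"temperature"`.
#' @param axis_values Strictly increasing numeric vector: minutes for a time
#'   axis, kelvin for a temperature axis. Defaults to the spectra's own
#'   time/temperature metadata.
#' @param file Optional character vector of source file names.
#' @return A `raman_series` tibble with columns `file`, `time_min` and/or
#'   `temperature_K`, `rh_percent`, and `spectrum`.
#' @export
raman_series <- function(spectra, axis = c("time", "temperature"),
                         axis_values = NULL, file = NULL) {
  axis <- match.arg(axis)
  if (!length(spectra)) {
    abort("A series needs at least one spectrum.",
          class = "ramankin_degenerate_error")
  }
  for (sp in spectra) stop_if_not_spectrum(sp)
  if (is.null(axis_values)) {
    axis_values <- vapply(
      spectra,
      function(sp) if (axis == "time") attr(sp, "time") else attr(sp, "temperature"),
      numeric(1)
    )
  }
  if (anyNA(axis_values)) {
    abort("Every spectrum needs a value on the series axis.",
          class = "ramankin_ordering_error")
  }
  if (any(diff(axis_values) <= 0)) {
    abort("Series axis values must be strictly increasing (no duplicates).",
          class = "ramankin_ordering_error")
  }
  grid <- spectra[[1]]$wavenumber
  same <- vapply(spectra, function(sp) {
    length(sp$wavenumber) == length(grid) && all(sp$wavenumber == grid)
  }, logical(1))
  if (!all(same)) {
    abort(paste0(
      "Spectra are not on a common wavenumber grid. ",
      "Use resample_common_grid() to put them on one."
    ), class = "ramankin_grid_error")
  }
  out <- tibble(
    file = file %||% rep(NA_character_, length(spectra)),
    time_min = vapply(spectra, function(sp) attr(sp, "time"), numeric(1)),
    temperature_K = vapply(spectra, function(sp) attr(sp, "temperature"), numeric(1)),
    rh_percent = vapply(spectra, function(sp) attr(sp, "rh"), numeric(1)),
    spectrum = spectra
  )
  if (axis == "time") out$time_min <- axis_values else out$temperature_K <- axis_values
  structure(out, class = c("raman_series", class(out)), axis = axis)
}

#' Series accessors
#'
#' @param series A `raman_series`.
#' @return `series_axis()` returns `"time"` or `"temperature"`;
#'   `series_axis_values()` the ordered axis values (minutes or kelvin);
#'   `series_grid()` the common wavenumber grid;
#'   `series_matrix()` an intensity matrix (spectra in columns).
#' @export
series_axis <- function(series) attr(series, "axis")

#' @rdname series_axis
#' @export
series_axis_values <- function(series) {
  if (series_axis(series) == "time") series$time_min else series$temperature_K
}

#' @rdname series_axis
#' @export
series_grid <- function(series) series$spectrum[[1]]$wavenumber

#' @rdname series_axis
#' @export
series_matrix <- function(series) {
  vapply(series$spectrum, function(sp) sp$intensity,
         numeric(nrow(series$spectrum[[1]])))
}

series_representation <- function(series) {
  reps <- vapply(series$spectrum, spectrum_representation, character(1))
  unique(reps)
}

stop_if_not_series <- function(x, arg = "series") {
  if (!inherits(x, "raman_series")) {
    abort(sprintf("`%s` must be a raman_series.", arg),
          class = "ramankin_type_error")
  }
  invisible(x)
}

# Replace the spectra of a series, keeping axis and per-row metadata.
series_update_spectra <- function(series, spectra) {
  raman_series(spectra,
    axis = series_axis(series),
    axis_values = series_axis_values(series),
    file = series$file
  )
}

#' @export
print.raman_series <- function(x, ...) {
  cat(sprintf(
    "<raman_series> %d spectra along a %s axis (%s), representation: %s\n",
    nrow(x), series_axis(x),
    paste(format(range(series_axis_values(x)), digits = 5), collapse = " to "),
    paste(series_representation(x), collapse = "/")
  ))
  NextMethod()
  invisible(x)
}
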