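#' Read a single spectrum from a two-column ASCII file
#'
#' Accepts whitespace-, comma- or semicolon-delimited two-column numeric
#' text. Lines starting with `#` are comments; structured comments of the
#' form `# key: value` written by [write_spectrum()] are parsed back as
#' metadata. Files written in descending wavenumber order are sorted
#' ascending (with a message), since both orders occur in spectrometer
#' exports.
#'
#' @param path File path.
#' @param representation,temperature,time,rh,label Optional metadata
#'   overrides; when given they take precedence over metadata found in the
#'   file header.
#' @return A `raman_spectrum` (representation `"raw"` unless overridden or
#'   recorded in the file).
#' @export
read_spectrum <- function(path, representation = NULL, temperature = NULL,
                          time = NULL, rh = NULL, label = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("Spectrum file not found: %s", path),
          class = "ramankin_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  header <- grep("^\\s*#", lines, value = TRUE)
  for (h in header) {
    m <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(.*\\S)\\s*$", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  body_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(body_idx) < 8) {
    abort(sprintf("Fewer than 8 data points in %s.", path),
          class = "ramankin_degenerate_error")
  }
  vals <- matrix(NA_real_, length(body_idx), 2)
  for (i in seq_along(body_idx)) {
    ln <- body_idx[i]
    fields <- strsplit(trimws(gsub("[,;]+", " ", lines[ln])), "\\s+")[[1]]
    if (length(fields) < 2) {
      abort(sprintf("Line %d of %s has fewer than two columns.", ln, path),
            class = "ramankin_parse_error")
    }
    num <- suppressWarnings(as.numeric(fields[1:2]))
    if (anyNA(num)) {
      abort(sprintf("Non-numeric value on line %d of %s: '%s'", ln, path, lines[ln]),
            class = "ramankin_parse_error")
    }
    vals[i, ] <- num
  }
  if (all(diff(vals[, 1]) < 0)) {
    message("Wavenumbers in ", path, " are descending; sorting ascending.")
    vals <- vals[rev(seq_len(nrow(vals))), , drop = FALSE]
  }
  num_meta <- function(key) if (is.null(meta[[key]])) NULL else as.numeric(meta[[key]])
  raman_spectrum(
    vals[, 1], vals[, 2],
    representation = representation %||% meta[["representation"]] %||% "raw",
    temperature = temperature %||% num_meta("temperature_K"),
    time = time %||% num_meta("time_min"),
    rh = rh %||% num_meta("rh_percent"),
    label = label %||% meta[["label"]]
  )
}

#' Write a spectrum to a two-column ASCII file
#'
#' Metadata are stored as `# key: value` header comments so that a
#' write/read round trip is lossless.
#'
#' @param spectrum A `raman_spectrum`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stop_if_not_spectrum(spectrum)
  m <- spectrum_meta(spectrum)
  header <- c(
    "# ramankin spectrum",
    sprintf("# representation: %s", m$representation),
    if (!is.na(m$temperature)) sprintf("# temperature_K: %.17g", m$temperature),
    if (!is.na(m$time)) sprintf("# time_min: %.17g", m$time),
    if (!is.na(m$rh)) sprintf("# rh_percent: %.17g", m$rh),
    if (!is.na(m$label)) sprintf("# label: %s", m$label)
  )
  body <- sprintf("%.17g %.17g", spectrum$wavenumber, spectrum$intensity)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ordered spectral series from a manifest
#'
#' The manifest is a CSV with a `file` column plus `time_min` and/or
#' `temperature_C` (and optional `rh_percent`). The series axis is inferred
#' from which column varies monotonically (time takes precedence when both
#' vary); temperatures are converted to kelvin internally
#' (K = degrees C + 273.15) because the Bose factor needs kelvin. Spectrum
#' paths are resolved relative to the manifest's directory.
#'
#' @param manifest Path to the manifest CSV.
#' @return A `raman_series`.
#' @export
read_series <- function(manifest) {
  if (!file.exists(manifest)) {
    abort(sprintf("Manifest not found: %s", manifest),
          class = "ramankin_io_error")
  }
  tab <- readr::read_csv(manifest, show_col_types = FALSE, progress = FALSE)
  if (!"file" %in% names(tab)) {
    abort("Manifest must have a `file` column.", class = "ramankin_parse_error")
  }
  has_time <- "time_min" %in% names(tab) && !anyNA(tab$time_min)
  has_temp <- "temperature_C" %in% names(tab) && !anyNA(tab$temperature_C)
  varies <- function(x) length(unique(x)) > 1
  axis <- if (has_time && (varies(tab$time_min) || !has_temp)) "time"
          else if (has_temp) "temperature"
          else abort("Manifest needs a varying `time_min` or `temperature_C` column.",
                     class = "ramankin_parse_error")
  axis_raw <- if (axis == "time") tab$time_min else tab$temperature_C + 273.15
  if (anyNA(axis_raw) || any(diff(axis_raw) <= 0)) {
    abort("Manifest axis values must be strictly increasing (no duplicates).",
          class = "ramankin_ordering_error")
  }
  dir <- dirname(manifest)
  spectra <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    p <- tab$file[i]
    if (!file.exists(p)) p <- file.path(dir, tab$file[i])
    spectra[[i]] <- read_spectrum(
      p,
      temperature = if ("temperature_C" %in% names(tab) && !is.na(tab$temperature_C[i]))
        tab$temperature_C[i] + 273.15 else NULL,
      time = if ("time_min" %in% names(tab) && !is.na(tab$time_min[i]))
        tab$time_min[i] else NULL,
      rh = if ("rh_percent" %in% names(tab) && !is.na(tab$rh_percent[i]))
        tab$rh_percent[i] else NULL
    )
  }
  raman_series(spectra, axis = axis, axis_values = axis_raw, file = tab$file)
}

#' Write a series as spectrum files plus a manifest
#'
#' @param series A `raman_series`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem for the individual spectra.
#' @return The manifest path, invisibly.
#' @export
write_series <- function(series, dir, stem = "spectrum") {
  stop_if_not_series(series)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- nrow(series)
  files <- sprintf("%s_%03d.txt", stem, seq_len(n))
  for (i in seq_len(n)) {
    write_spectrum(series$spectrum[[i]], file.path(dir, files[i]))
  }
  man <- tibble(
    file = files,
    time_min = series$time_min,
    temperature_C = series$temperature_K - 273.15,
    rh_percent = series$rh_percent
  )
  manifest <- file.path(dir, "manifest.csv")
  readr::write_csv(man, manifest)
  invisible(manifest)
}

#' Resample a series onto a common wavenumber grid
#'
#' Linear interpolation of every spectrum onto `grid`; metadata are
#' preserved. The grid must lie inside the intersection of all spectra
#' ranges (no extrapolation).
#'
#' @param series A `raman_series`.
#' @param grid Target wavenumber grid, cm^-1, strictly increasing.
#' @return A `raman_series` on `grid`.
#' @export
resample_common_grid <- function(series, grid) {
  stop_if_not_series(series)
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) {
    abort("`grid` must be strictly increasing.", class = "ramankin_data_error")
  }
  for (sp in series$spectrum) {
    if (min(grid) < min(sp$wavenumber) || max(grid) > max(sp$wavenumber)) {
      abort("Grid lies outside a spectrum's range; extrapolation is not performed.",
            class = "ramankin_extrapolation_error")
    }
  }
  spectra <- lapply(series$spectrum, function(sp) {
    y <- approx(sp$wavenumber, sp$intensity, xout = grid)$y
    spectrum_update(sp, wavenumber = grid, intensity = y)
  })
  series_update_spectra(series, spectra)
}
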