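#' Decompose a low-frequency spectrum into QES, VDOS and phonon peaks
#'
#' Fits the spectrum over `window` as a sum of the template's components
#' (zero-centered Lorentzian quasi-elastic scattering, lognormal
#' vibrational density of states, pseudo-Voigt phonon peaks) by bounded
#' Levenberg-Marquardt least squares. The template supplies initial values
#' and box bounds; no automatic peak detection is attempted. Parameter
#' standard errors come from the local curvature (Jacobian cross-product)
#' at the solution.
#'
#' The quasi-elastic intensity `I_QES` is reported as the integrated
#' Lorentzian area over the fit window,
#' `amplitude * hwhm * (atan(hi / hwhm) - atan(lo / hwhm))`, which is more
#' robust than the peak amplitude under the amplitude/width trade-off.
#'
#' @param spectrum A reduced or susceptibility `raman_spectrum` covering
#'   `window`.
#' @param template A list of [spectral_components] (or a single component).
#' @param window Fit window `c(lo, hi)` in cm^-1; default `c(5, 150)`, the
#'   conventional low-frequency Raman range.
#' @param weights Optional per-point weights (default uniform).
#' @param max_iter Optimizer iteration cap (default 500).
#' @return A `decomposition_fit` object; see [tidy()] and [glance()]
#'   methods.
#' @export
fit_decomposition <- function(spectrum, template, window = c(5, 150),
                              weights = NULL, max_iter = 500) {
  stop_if_not_spectrum(spectrum)
  if (!spectrum_representation(spectrum) %in% c("reduced", "susceptibility")) {
    abort("Decomposition expects a reduced or susceptibility spectrum.",
          class = "ramankin_representation_error")
  }
  template <- check_template(template)
  keep <- spectrum$wavenumber >= window[1] & spectrum$wavenumber <= window[2]
  if (sum(keep) < 8) {
    abort("The fit window covers too little of the spectrum.",
          class = "ramankin_domain_error")
  }
  omega <- spectrum$wavenumber[keep]
  y <- spectrum$intensity[keep]
  if (any(!is.finite(y))) {
    abort("Non-finite intensities inside the fit window.",
          class = "ramankin_data_error")
  }
  w <- weights %||% rep(1, length(y))
  sw <- sqrt(w)

  # Phonon positions default to the fit window when unbounded.
  template <- lapply(template, function(comp) {
    if (comp$type == "phonon") {
      if (!is.finite(comp$lower[["position"]])) comp$lower[["position"]] <- window[1]
      if (!is.finite(comp$upper[["position"]])) comp$upper[["position"]] <- window[2]
    }
    comp
  })

  sizes <- vapply(template, function(c) length(c$par), integer(1))
  par0 <- unlist(lapply(template, `[[`, "par"))
  lower <- unlist(lapply(template, `[[`, "lower"))
  upper <- unlist(lapply(template, `[[`, "upper"))
  split_par <- function(p) {
    out <- vector("list", length(template))
    at <- 0
    for (i in seq_along(template)) {
      out[[i]] <- setNames(p[at + seq_len(sizes[i])], names(template[[i]]$par))
      at <- at + sizes[i]
    }
    out
  }
  resid_fn <- function(p) (eval_template(template, omega, split_par(p)) - y) * sw

  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ftol = 1e-15, ptol = 1e-15, gtol = 0
    )
  )
  p_hat <- fit$par
  converged <- fit$info %in% c(1, 2, 3, 4) && fit$niter < max_iter

  n <- length(y)
  p <- length(p_hat)
  rss <- sum(fit$fvec^2)
  sigma2 <- if (n > p) rss / (n - p) else NA_real_
  se <- rep(NA_real_, p)
  covm <- NULL
  if (is.finite(sigma2)) {
    covm <- tryCatch(sigma2 * chol2inv(chol(fit$hessian)), error = function(e) NULL)
    if (!is.null(covm)) se <- sqrt(pmax(diag(covm), 0))
  }

  par_list <- split_par(p_hat)
  comp_tbl <- purrr::map_dfr(seq_along(template), function(i) {
    tibble(
      component = i,
      type = template[[i]]$type,
      term = names(template[[i]]$par),
      estimate = unname(par_list[[i]]),
      std.error = se[cumsum(sizes)[i] - sizes[i] + seq_len(sizes[i])]
    )
  })

  fitted <- eval_template(template, omega, par_list)
  residual_rms <- sqrt(mean((fitted - y)^2))

  # Integrated QES area over the window (+ delta-method uncertainty).
  i_qes <- i_qes_se <- NA_real_
  qes_idx <- which(vapply(template, function(c) c$type == "qes", logical(1)))
  if (length(qes_idx)) {
    qes_area <- function(a, g) a * g * (atan(window[2] / g) - atan(window[1] / g))
    i_qes <- sum(vapply(qes_idx, function(i) {
      qes_area(par_list[[i]][["amplitude"]], par_list[[i]][["hwhm"]])
    }, numeric(1)))
    if (!is.null(covm)) {
      grad <- numeric(p)
      at <- c(0, cumsum(sizes))
      for (i in qes_idx) {
        a <- par_list[[i]][["amplitude"]]; g <- par_list[[i]][["hwhm"]]
        h <- max(g * 1e-6, 1e-9)
        grad[at[i] + 1] <- qes_area(1, g)
        grad[at[i] + 2] <- (qes_area(a, g + h) - qes_area(a, g - h)) / (2 * h)
      }
      i_qes_se <- sqrt(max(drop(t(grad) %*% covm %*% grad), 0))
    }
  }

  structure(
    list(
      components = comp_tbl,
      template = template,
      par = p_hat,
      data = tibble(wavenumber = omega, intensity = y,
                    fitted = fitted, residual = y - fitted),
      residual_rms = residual_rms,
      converged = converged,
      window = window,
      i_qes = i_qes,
      i_qes_se = i_qes_se,
      niter = fit$niter,
      nobs = n
    ),
    class = "decomposition_fit"
  )
}

#' @export
print.decomposition_fit <- function(x, ...) {
  cat(sprintf(
    "<decomposition_fit> %d components over %g-%g cm-1, residual RMS %.4g%s\n",
    length(x$template), x$window[1], x$window[2], x$residual_rms,
    if (x$converged) "" else " (NOT converged)"
  ))
  if (!is.na(x$i_qes)) cat(sprintf("  I_QES (window area): %.6g\n", x$i_qes))
  print(x$components)
  invisible(x)
}

#' @rdname fit_decomposition
#' @param x A `decomposition_fit`.
#' @param ... Unused.
#' @method tidy decomposition_fit
#' @export
tidy.decomposition_fit <- function(x, ...) x$components

#' @rdname fit_decomposition
#' @method glance decomposition_fit
#' @export
glance.decomposition_fit <- function(x, ...) {
  tibble(
    residual_rms = x$residual_rms,
    i_qes = x$i_qes,
    i_qes_se = x$i_qes_se,
    converged = x$converged,
    niter = x$niter,
    nobs = x$nobs
  )
}

# Re-seed a template's initial values from fitted estimates, clamped inside
# the bounds (used to warm-start successive fits along a series).
warm_start_template <- function(template, fit) {
  par_list <- split(fit$components$estimate,
                    rep(seq_along(template),
                        vapply(template, function(c) length(c$par), integer(1))))
  for (i in seq_along(template)) {
    p <- setNames(par_list[[i]], names(template[[i]]$par))
    template[[i]]$par <- pmin(pmax(p, template[[i]]$lower), template[[i]]$upper)
  }
  template
}

#' Quasi-elastic intensity trace along a spectral series
#'
#' Fits the decomposition to every spectrum of a preprocessed series (in
#' axis order, each fit warm-started from the previous one) and returns
#' the integrated quasi-elastic intensity against the series axis. A
#' non-converged individual fit is flagged in the output, not raised as an
#' error, so a long ramp survives one misbehaving spectrum.
#'
#' @param series A `raman_series` in reduced or susceptibility
#'   representation.
#' @inheritParams fit_decomposition
#' @return A tibble with the axis column (`time_min` or `temperature_K`),
#'   `i_qes`, `i_qes_se`, `residual_rms` and `converged`.
#' @export
qes_trace <- function(series, template, window = c(5, 150), max_iter = 500) {
  stop_if_not_series(series)
  template <- check_template(template)
  axis_col <- if (series_axis(series) == "time") "time_min" else "temperature_K"
  vals <- series_axis_values(series)
  rows <- vector("list", nrow(series))
  current <- template
  for (i in seq_len(nrow(series))) {
    fit <- tryCatch(
      fit_decomposition(series$spectrum[[i]], current,
                        window = window, max_iter = max_iter),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      rows[[i]] <- tibble(i_qes = NA_real_, i_qes_se = NA_real_,
                          residual_rms = NA_real_, converged = FALSE)
    } else {
      rows[[i]] <- tibble(i_qes = fit$i_qes, i_qes_se = fit$i_qes_se,
                          residual_rms = fit$residual_rms,
                          converged = fit$converged)
      if (fit$converged) current <- warm_start_template(current, fit)
    }
  }
  out <- dplyr::bind_rows(rows)
  out[[axis_col]] <- vals
  dplyr::relocate(out, dplyr::all_of(axis_col))
}
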