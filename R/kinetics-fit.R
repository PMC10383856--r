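#' Fit a kinetic model to a transformation curve
#'
#' Nonlinear least squares on rho(t) by Levenberg-Marquardt, with the rate
#' constant fitted on a log scale for conditioning. The Avrami fit is
#' initialized by the Sharp-Hancock linearization (the slope of
#' ln(-ln(1 - rho)) against ln t estimates n, the intercept ln k);
#' one-parameter models start from the median of g(rho)/t. By default only
#' points with rho inside `rho_window` (0.05-0.95) enter the fit, keeping
#' baseline and saturation plateaus from biasing the mechanism parameters;
#' widen the window to override. Standard errors are asymptotic
#' (curvature-based).
#'
#' @param curve A `transformation_curve` (or data frame with `time_min`
#'   and `rho`).
#' @param model Model id, e.g. `"avrami"`, `"D3"` (alias `"jander"`); see
#'   [kinetic_models()].
#' @param rho_window Keep points with rho in this closed interval
#'   (default `c(0.05, 0.95)`); at least 6 are required.
#' @param max_iter Optimizer iteration cap.
#' @return A `kinetic_fit` object with elements `model`, `k`, `n`,
#'   `k_se`, `n_se`, `r_squared`, `aicc`, `converged`, `data`; see the
#'   [tidy()] and [glance()] methods.
#' @export
fit_kinetics <- function(curve, model = "avrami",
                         rho_window = c(0.05, 0.95), max_iter = 500) {
  curve <- as_transformation_curve(curve)
  m <- get_kinetic_model(model)
  keep <- curve$rho >= rho_window[1] & curve$rho <= rho_window[2] &
    curve$time_min > 0
  t <- curve$time_min[keep]
  r <- curve$rho[keep]
  if (length(t) < 6) {
    abort("Need at least 6 points with rho inside the fit window.",
          class = "ramankin_data_error")
  }

  two_par <- m$n_params == 2
  if (two_par) {
    # Sharp-Hancock initialization on the interior points.
    ok <- r > 0 & r < 1
    sh <- lm(log(-log1p(-r[ok])) ~ log(t[ok]))
    n0 <- max(unname(coef(sh)[2]), 0.05)
    k0 <- exp(unname(coef(sh)[1]))
    par0 <- c(logk = log(k0), n = n0)
    lower <- c(logk = -Inf, n = 0.01)
    upper <- c(logk = Inf, n = 20)
    predict_rho <- function(p, t) m$rho_of_t(t, exp(p[["logk"]]), p[["n"]])
  } else {
    gr <- m$g(r)
    k0 <- median(gr / t)
    par0 <- c(logk = log(k0))
    lower <- c(logk = -Inf)
    upper <- c(logk = Inf)
    predict_rho <- function(p, t) model_rho(m, exp(p[["logk"]]), t)
  }

  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper,
    fn = function(p) predict_rho(p, t) - r,
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ftol = 1e-15, ptol = 1e-15, gtol = 0
    )
  )
  p_hat <- fit$par
  converged <- fit$info %in% c(1, 2, 3, 4) && fit$niter < max_iter

  nobs <- length(t)
  p <- length(p_hat)
  rss <- sum(fit$fvec^2)
  sigma2 <- if (nobs > p) rss / (nobs - p) else NA_real_
  se <- rep(NA_real_, p)
  if (is.finite(sigma2)) {
    covm <- tryCatch(sigma2 * chol2inv(chol(fit$hessian)), error = function(e) NULL)
    if (!is.null(covm)) se <- sqrt(pmax(diag(covm), 0))
  }

  k_hat <- exp(p_hat[["logk"]])
  k_se <- k_hat * se[1] # delta method for the log-scale parameter
  n_hat <- if (two_par) p_hat[["n"]] else NA_real_
  n_se <- if (two_par) se[2] else NA_real_

  tss <- sum((r - mean(r))^2)
  r_squared <- if (tss > 0) 1 - rss / tss else NA_real_
  # AICc for Gaussian residuals; +1 parameter for the residual variance.
  # RSS below numerical precision (noiseless data fitted exactly) is
  # floored so that exact fits tie and the ranking falls to parsimony.
  p_eff <- p + 1
  rss_eff <- max(rss, nobs * 1e-20)
  aicc <- if (nobs > p_eff + 1) {
    nobs * log(rss_eff / nobs) + 2 * p_eff +
      2 * p_eff * (p_eff + 1) / (nobs - p_eff - 1)
  } else {
    NA_real_
  }

  structure(
    list(
      model = m$id, mechanism = m$mechanism,
      k = k_hat, k_se = k_se, n = n_hat, n_se = n_se,
      r_squared = r_squared, aicc = aicc, rss = rss,
      converged = converged, nobs = nobs, n_params = p,
      rho_window = rho_window,
      data = tibble(time_min = t, rho = r,
                    fitted = predict_rho(p_hat, t),
                    residual = r - predict_rho(p_hat, t))
    ),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> %s (%s)%s\n", x$model, x$mechanism,
              if (x$converged) "" else " [NOT converged]"))
  cat(sprintf("  k = %.6g +/- %.2g %s\n", x$k, x$k_se,
              if (!is.na(x$n)) "min^-n" else "min^-1"))
  if (!is.na(x$n)) cat(sprintf("  n = %.4f +/- %.4f\n", x$n, x$n_se))
  cat(sprintf("  R^2 = %.6f, AICc = %.2f, points = %d\n",
              x$r_squared, x$aicc, x$nobs))
  invisible(x)
}

#' @rdname fit_kinetics
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @method tidy kinetic_fit
#' @export
tidy.kinetic_fit <- function(x, ...) {
  out <- tibble(term = "k", estimate = x$k, std.error = x$k_se)
  if (!is.na(x$n)) {
    out <- dplyr::bind_rows(out,
      tibble(term = "n", estimate = x$n, std.error = x$n_se))
  }
  out
}

#' @rdname fit_kinetics
#' @method glance kinetic_fit
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble(
    model = x$model, k = x$k, n = x$n,
    r.squared = x$r_squared, aicc = x$aicc,
    converged = x$converged, nobs = x$nobs
  )
}

#' Fit a catalog of kinetic models and rank them
#'
#' Fits every model of the catalog to the curve and ranks them by AICc
#' (ascending: lower is better). The ranking is deterministic: AICc ties
#' are broken by fewer parameters, then by lexical model id. A model whose
#' fit fails outright is kept in the table with `NA` scores and ranked
#' last.
#'
#' @inheritParams fit_kinetics
#' @param models Character vector of model ids (default: the full
#'   catalog).
#' @return A `kinetic_ranking` tibble with columns `rank`, `model`,
#'   `n_params`, `k`, `n`, `r_squared`, `aicc`, `delta_aicc`, `converged`
#'   and a `fit` list-column of `kinetic_fit` objects.
#' @export
select_model <- function(curve, models = kinetic_models()$model,
                         rho_window = c(0.05, 0.95)) {
  if (!length(models)) {
    abort("The model catalog must not be empty.", class = "ramankin_spec_error")
  }
  curve <- as_transformation_curve(curve)
  fits <- lapply(models, function(id) {
    tryCatch(fit_kinetics(curve, id, rho_window = rho_window),
             error = function(e) NULL)
  })
  tbl <- purrr::map_dfr(seq_along(models), function(i) {
    f <- fits[[i]]
    if (is.null(f)) {
      tibble(model = models[i],
             n_params = get_kinetic_model(models[i])$n_params,
             k = NA_real_, n = NA_real_, r_squared = NA_real_,
             aicc = NA_real_, converged = FALSE)
    } else {
      tibble(model = f$model, n_params = f$n_params, k = f$k, n = f$n,
             r_squared = f$r_squared, aicc = f$aicc, converged = f$converged)
    }
  })
  tbl$fit <- fits
  ord <- order(is.na(tbl$aicc), tbl$aicc, tbl$n_params, tbl$model)
  tbl <- tbl[ord, ]
  tbl$rank <- seq_len(nrow(tbl))
  tbl$delta_aicc <- tbl$aicc - tbl$aicc[1]
  out <- dplyr::relocate(tbl, "rank")
  structure(out, class = c("kinetic_ranking", class(out)))
}
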