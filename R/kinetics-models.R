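#' Solid-state kinetic model catalog
#'
#' Classical integral models g(rho) = k t for isothermal solid-state
#' transformations, plus the Avrami nucleation-and-growth law written in
#' the convention `rho(t) = 1 - exp(-k * t^n)` (so k has units min^-n;
#' see [avrami_k_convert()] for the (k t)^n convention). Catalog:
#'
#' | id       | mechanism                                   | g(rho)                           |
#' |----------|---------------------------------------------|----------------------------------|
#' | `avrami` | nucleation and growth, exponent n           | -ln(1 - rho) ( = k t^n )         |
#' | `D1`     | one-dimensional diffusion                   | rho^2                            |
#' | `D2`     | two-dimensional diffusion                   | (1-rho) ln(1-rho) + rho          |
#' | `D3`     | three-dimensional diffusion (Jander)        | (1 - (1-rho)^(1/3))^2            |
#' | `D4`     | 3-D diffusion (Ginstling-Brounshtein)       | 1 - 2 rho/3 - (1-rho)^(2/3)      |
#' | `R2`     | contracting area (phase boundary)           | 1 - (1-rho)^(1/2)                |
#' | `R3`     | contracting volume (phase boundary)         | 1 - (1-rho)^(1/3)                |
#' | `F1`     | first order (random nucleation)             | -ln(1 - rho)                     |
#'
#' `D2` and `D4` have no closed-form rho(t); those are inverted by a
#' vectorized bisection accurate to ~1e-15. New models can be added with
#' [register_kinetic_model()].
#'
#' @return `kinetic_models()` returns a tibble with columns `model`,
#'   `mechanism`, `n_params`.
#' @export
kinetic_models <- function() {
  ids <- ls(.kinetic_registry)
  tbl <- purrr::map_dfr(ids, function(id) {
    m <- .kinetic_registry[[id]]
    tibble(model = m$id, mechanism = m$mechanism, n_params = m$n_params)
  })
  dplyr::arrange(tbl, dplyr::desc(.data$model == "avrami"), .data$model)
}

.kinetic_registry <- new.env(parent = emptyenv())

#' @rdname kinetic_models
#' @param id Model tag.
#' @param mechanism Human-readable mechanism description.
#' @param g Integral form: function of rho.
#' @param rho_of_t Closed-form rho(t, k, n), or `NULL` to invert `g`
#'   numerically (then `g` must be monotone increasing on \[0, 1\]).
#' @param n_params Number of fitted parameters (1, or 2 for Avrami-like).
#' @param g_complete Value of g at rho = 1 (conversion completes when
#'   k t reaches it).
#' @export
register_kinetic_model <- function(id, mechanism, g, rho_of_t = NULL,
                                   n_params = 1, g_complete = g(1)) {
  assign(id, list(id = id, mechanism = mechanism, g = g,
                  rho_of_t = rho_of_t, n_params = n_params,
                  g_complete = g_complete),
         envir = .kinetic_registry)
  invisible(id)
}

get_kinetic_model <- function(model) {
  if (is.list(model) && !is.null(model$id)) return(model)
  id <- as.character(model)
  if (identical(tolower(id), "jander")) id <- "D3"
  if (identical(tolower(id), "avrami")) id <- "avrami"
  if (!exists(id, envir = .kinetic_registry, inherits = FALSE)) {
    abort(sprintf("Unknown kinetic model '%s'. See kinetic_models().", model),
          class = "ramankin_lookup_error")
  }
  .kinetic_registry[[id]]
}

# Vectorized bisection for rho with g(rho) = x, g monotone increasing.
invert_g <- function(g, x, g_complete) {
  x <- pmin(pmax(x, 0), g_complete)
  lo <- rep(0, length(x))
  hi <- rep(1, length(x))
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    up <- g(mid) < x
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  (lo + hi) / 2
}

#' Evaluate a kinetic model
#'
#' `model_rho()` gives the transformation fraction rho(t) for rate
#' constant `k` (and exponent `n` for Avrami); `model_g()` evaluates the
#' integral form g(rho). For the one-parameter catalog models
#' g(rho(t)) = k t until conversion completes; for Avrami
#' g(rho(t)) = -ln(1 - rho(t)) = k t^n.
#'
#' @param model Model id (see [kinetic_models()]) or a registered model
#'   object.
#' @param k Rate constant, > 0 (min^-1, or min^-n for Avrami).
#' @param t Times in minutes, >= 0.
#' @param n Avrami exponent, > 0 (ignored by one-parameter models).
#' @param rho Transformation fraction(s) in \[0, 1\].
#' @return Numeric vector.
#' @examples
#' model_g("D3", 0.5) # Jander half-conversion: (1 - 0.5^(1/3))^2
#' model_rho("avrami", k = log(2), n = 1, t = 1) # 0.5
#' @export
model_rho <- function(model, k, t, n = NULL) {
  m <- get_kinetic_model(model)
  if (k <= 0) abort("`k` must be > 0.", class = "ramankin_domain_error")
  if (any(t < 0)) abort("`t` must be >= 0.", class = "ramankin_domain_error")
  if (m$n_params == 2) {
    if (is.null(n) || n <= 0) {
      abort("This model needs an exponent `n` > 0.",
            class = "ramankin_domain_error")
    }
    return(m$rho_of_t(t, k, n))
  }
  if (!is.null(m$rho_of_t)) m$rho_of_t(t, k) else invert_g(m$g, k * t, m$g_complete)
}

#' @rdname model_rho
#' @export
model_g <- function(model, rho) {
  m <- get_kinetic_model(model)
  if (any(rho < 0 | rho > 1)) {
    abort("`rho` must lie in [0, 1].", class = "ramankin_domain_error")
  }
  m$g(rho)
}

#' Convert Avrami rate constants between conventions
#'
#' Between `rho = 1 - exp(-k * t^n)` (k in min^-n, the convention used
#' throughout this package) and `rho = 1 - exp(-(k1 * t)^n)` (k1 in
#' min^-1): `k1 = k^(1/n)`.
#'
#' @param k Rate constant in the `k * t^n` convention.
#' @param n Avrami exponent.
#' @param to `"per_min"` (k -> k1) or `"per_min_n"` (k1 -> k).
#' @return Converted rate constant.
#' @export
avrami_k_convert <- function(k, n, to = c("per_min", "per_min_n")) {
  to <- match.arg(to)
  if (to == "per_min") k^(1 / n) else k^n
}

local({
  register_kinetic_model(
    "avrami", "nucleation and growth (Avrami), rho = 1 - exp(-k t^n)",
    g = function(rho) -log1p(-rho),
    rho_of_t = function(t, k, n) -expm1(-k * t^n),
    n_params = 2, g_complete = Inf
  )
  register_kinetic_model(
    "D1", "one-dimensional diffusion",
    g = function(rho) rho^2,
    rho_of_t = function(t, k) pmin(sqrt(pmax(k * t, 0)), 1)
  )
  register_kinetic_model(
    "D2", "two-dimensional diffusion",
    g = function(rho) ifelse(rho >= 1, 1, (1 - rho) * log1p(-rho) + rho),
    g_complete = 1
  )
  register_kinetic_model(
    "D3", "three-dimensional diffusion (Jander)",
    g = function(rho) (1 - (1 - rho)^(1 / 3))^2,
    rho_of_t = function(t, k) {
      x <- pmin(pmax(k * t, 0), 1)
      1 - (1 - sqrt(x))^3
    }
  )
  register_kinetic_model(
    "D4", "three-dimensional diffusion (Ginstling-Brounshtein)",
    g = function(rho) 1 - 2 * rho / 3 - (1 - rho)^(2 / 3),
    g_complete = 1 / 3
  )
  register_kinetic_model(
    "R2", "contracting area (phase-boundary controlled)",
    g = function(rho) 1 - sqrt(1 - rho),
    rho_of_t = function(t, k) {
      x <- pmin(pmax(k * t, 0), 1)
      1 - (1 - x)^2
    }
  )
  register_kinetic_model(
    "R3", "contracting volume (phase-boundary controlled)",
    g = function(rho) 1 - (1 - rho)^(1 / 3),
    rho_of_t = function(t, k) {
      x <- pmin(pmax(k * t, 0), 1)
      1 - (1 - x)^3
    }
  )
  register_kinetic_model(
    "F1", "first order (random nucleation)",
    g = function(rho) -log1p(-rho),
    rho_of_t = function(t, k) -expm1(-k * t),
    g_complete = Inf
  )
})
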