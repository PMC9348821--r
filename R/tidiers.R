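#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a slope fit
#'
#' @param x A `slope_fit` from [fit_rate()].
#' @param ... Unused.
#' @return A one-row tibble: `slope`, `se_slope`, `ci_lo`, `ci_hi`,
#'   `intercept`, `n`, `window_start`, `window_end`, `normalized`.
#' @exportS3Method generics::tidy
tidy.slope_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, se_slope = x$se_slope,
    ci_lo = unname(x$ci95[1]), ci_hi = unname(x$ci95[2]),
    intercept = x$intercept, n = x$n_points,
    window_start = x$window[1], window_end = x$window[2],
    normalized = x$normalized
  )
}

#' @rdname tidy.slope_fit
#' @exportS3Method generics::glance
glance.slope_fit <- function(x, ...) {
  s <- quiet_perfect_fit(summary(x$fit))
  tibble::tibble(r.squared = s$r.squared, sigma = s$sigma,
                 df.residual = x$fit$df.residual, nobs = x$n_points)
}

#' Tidy an exhaustion estimate
#'
#' @param x An `exhaustion_estimate` from [stex()] or [stex_app()].
#' @param ... Unused.
#' @return A one-row tibble: `kind`, `hours_after_dawn`, `se` (single
#'   extrapolation only), `ci_lo`, `ci_hi`, `n_fits`.
#' @exportS3Method generics::tidy
tidy.exhaustion_estimate <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, hours_after_dawn = x$hours_after_dawn,
    se = if (x$kind == "StEx") x$se else NA_real_,
    ci_lo = unname(x$ci95[1]), ci_hi = unname(x$ci95[2]),
    n_fits = x$n_fits
  )
}

#' Tidy a nonlinearity result
#'
#' @param x A `nonlinearity_result` from [nonlinearity()].
#' @param ... Unused.
#' @return The per-time-point residue tibble (`zt`, `observed`,
#'   `predicted`, `residue`); `glance()` gives the one-row summary.
#' @exportS3Method generics::tidy
tidy.nonlinearity_result <- function(x, ...) {
  x$per_point_residues
}

#' @rdname tidy.nonlinearity_result
#' @exportS3Method generics::glance
glance.nonlinearity_result <- function(x, ...) {
  tibble::tibble(score = x$score, ci_lo = unname(x$ci95[1]),
                 ci_hi = unname(x$ci95[2]),
                 n_interior = x$n_interior_points, n_boot = x$n_boot)
}

#' Tidy a rhythm feature
#'
#' @param x A `rhythm_feature` from [peak_time()] or [amplitude()].
#' @param ... Unused.
#' @return A one-row tibble with whichever of the peak and amplitude
#'   fields the object carries.
#' @exportS3Method generics::tidy
tidy.rhythm_feature <- function(x, ...) {
  tibble::tibble(
    peak_zt = x$peak_zt %||% NA_real_,
    peak_lo = if (!is.null(x$peak_ci95)) unname(x$peak_ci95[1]) else NA_real_,
    peak_hi = if (!is.null(x$peak_ci95)) unname(x$peak_ci95[2]) else NA_real_,
    scorable = x$scorable %||% NA,
    amplitude = x$amplitude %||% NA_real_,
    amp_se = x$se %||% NA_real_,
    amp_lo = if (!is.null(x$amplitude_ci95)) unname(x$amplitude_ci95[1]) else NA_real_,
    amp_hi = if (!is.null(x$amplitude_ci95)) unname(x$amplitude_ci95[2]) else NA_real_
  )
}

#' Tidy a slope comparison
#'
#' @param x A `slope_comparison` from [compare_slopes()].
#' @param ... Unused.
#' @return A one-row tibble: `f_interaction`, `p_interaction`,
#'   `ss_interaction`, `df`, `stars`.
#' @exportS3Method generics::tidy
tidy.slope_comparison <- function(x, ...) {
  tibble::tibble(
    f_interaction = x$f_interaction, p_interaction = x$p_interaction,
    ss_interaction = x$ss_interaction, df = x$df,
    stars = sig_stars(x$p_interaction)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
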