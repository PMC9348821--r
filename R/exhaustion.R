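#' Project the time of starch exhaustion by single extrapolation (StEx)
#'
#' Fits the night-time mobilization line (all time points between dusk and
#' dawn, replicates unaveraged) and extrapolates it to zero starch. The
#' root of `f(ZT) = intercept + slope * ZT` is located with a bracketed,
#' derivative-free root finder over `[dusk, dusk + 3 * cycle_length]`.
#' The standard error of the projected time is obtained by the delta
#' method on the x-intercept `-b/m` using the intercept/slope covariance
#' of the fit:
#' `var(-b/m) = var(b)/m^2 + b^2 var(m)/m^4 - 2 b cov(b, m)/m^3`.
#'
#' @param data A single-series tidy starch tibble.
#' @param window Optional ZT window for the mobilization fit; defaults to
#'   dusk-to-dawn. Pass `c(dusk, dusk + 8.5)` to apply the common-darkness
#'   cap used in cross-T-cycle comparisons.
#' @return An object of class `exhaustion_estimate` with `kind = "StEx"`,
#'   `hours_after_dawn`, `se`, `ci95`, the underlying [fit_rate()] result,
#'   and a `degenerate` flag (root earlier than dusk).
#' @examples
#' s <- simulate_starch(starch_model(noise_frac = 0), light_regime(24, 12))
#' stex(s)
#' @export
stex <- function(data, window = NULL) {
  regime <- regime_from_data(data)
  dusk <- effective_dusk_zt(regime)
  if (is.null(window)) window <- c(dusk, regime$cycle_length_h)
  fit <- fit_rate(data, window = window)
  if (fit$slope >= 0) {
    rlang::abort("mobilization slope is non-negative: no projected exhaustion",
                 class = "dielstarch_no_exhaustion")
  }
  f <- function(z) fit$intercept + fit$slope * z
  upper <- dusk + 3 * regime$cycle_length_h
  degenerate <- FALSE
  if (f(dusk) <= 0) {
    # starch already projected <= 0 at dusk: root precedes the night
    root <- -fit$intercept / fit$slope
    degenerate <- TRUE
  } else if (f(upper) > 0) {
    rlang::abort("no root within three cycle lengths of dusk",
                 class = "dielstarch_no_exhaustion")
  } else {
    root <- stats::uniroot(f, lower = dusk, upper = upper,
                           tol = 1e-12)$root
  }
  vc <- quiet_perfect_fit(stats::vcov(fit$fit))
  b <- fit$intercept; m <- fit$slope
  var_root <- vc[1, 1] / m^2 + b^2 * vc[2, 2] / m^4 -
    2 * b * vc[1, 2] / m^3
  se <- sqrt(max(var_root, 0))
  tcrit <- stats::qt(0.975, df = fit$n_points - 2)
  structure(
    list(kind = "StEx", hours_after_dawn = root, se = se,
         ci95 = c(lo = root - tcrit * se, hi = root + tcrit * se),
         n_fits = 1L, windows = list(fit$window), fit = fit,
         degenerate = degenerate),
    class = "exhaustion_estimate"
  )
}

#' Project starch exhaustion by nested extrapolation (apparent StEx)
#'
#' Estimates the *initial* rate of mobilization by fitting a family of
#' nested windows, each anchored at dusk and extended point by point into
#' the night (never fewer than three time points, never beyond
#' `max_darkness_h` hours of darkness), extrapolating each fit to zero
#' starch, and aggregating the roots as a geometric mean. The 95% CI is a
#' Student-t interval on the log-scale mean of the roots, exponentiated —
#' consistent with geometric-mean aggregation. Capping the window (default
#' 8.5 h, a T17 night) makes estimates comparable across T-cycles and
#' shields the projection from the late-night slowdown of mobilization.
#'
#' @param data A single-series tidy starch tibble.
#' @param max_darkness_h Hours of darkness beyond dusk usable in fits.
#' @return An `exhaustion_estimate` with `kind = "StEx_app"`,
#'   `hours_after_dawn` (geometric mean), `ci95`, `n_fits`, per-window
#'   roots and windows.
#' @examples
#' s <- simulate_starch(starch_model(noise_frac = 0), light_regime(24, 12))
#' stex_app(s)
#' @export
stex_app <- function(data, max_darkness_h = 8.5) {
  regime <- regime_from_data(data)
  dusk <- effective_dusk_zt(regime)
  zts <- sort(unique(data$zt))
  night_zts <- zts[zts >= dusk - 1e-9 &
                     zts <= dusk + max_darkness_h + 1e-9]
  if (length(night_zts) < 3) {
    rlang::abort(
      sprintf("need >= 3 time points within %g h of dusk, found %d",
              max_darkness_h, length(night_zts)),
      class = "dielstarch_insufficient_data"
    )
  }
  roots <- c(); windows <- list()
  for (k in 3:length(night_zts)) {
    win <- c(night_zts[1], night_zts[k])
    fit <- fit_rate(data, window = win)
    root <- -fit$intercept / fit$slope
    # a non-negative (or numerically zero) slope never projects to zero
    # within a sensible horizon
    if (fit$slope >= 0 || !is.finite(root) ||
        root > dusk + 3 * regime$cycle_length_h) {
      rlang::warn(sprintf("nested window ZT%g-ZT%g does not project to exhaustion; excluded",
                          win[1], win[2]))
      next
    }
    roots <- c(roots, root)
    windows <- c(windows, list(win))
  }
  if (length(roots) == 0) {
    rlang::abort("every nested window had a non-negative slope",
                 class = "dielstarch_no_exhaustion")
  }
  logr <- log(roots)
  gm <- exp(mean(logr))
  n <- length(roots)
  if (n > 1 && stats::sd(logr) > 0) {
    se_log <- stats::sd(logr) / sqrt(n)
    tcrit <- stats::qt(0.975, df = n - 1)
    ci <- exp(mean(logr) + c(-1, 1) * tcrit * se_log)
  } else {
    ci <- c(gm, gm)
  }
  structure(
    list(kind = "StEx_app", hours_after_dawn = gm,
         ci95 = c(lo = ci[1], hi = ci[2]), n_fits = n,
         roots = roots, windows = windows),
    class = "exhaustion_estimate"
  )
}

#' Shift in projected exhaustion time between two conditions
#'
#' @param a,b `exhaustion_estimate` objects (or bare hours), e.g. the same
#'   genotype in a T17 and a T28 cycle.
#' @return `b - a` in hours.
#' @export
stex_shift <- function(a, b) {
  h <- function(x) if (inherits(x, "exhaustion_estimate")) x$hours_after_dawn else x
  h(b) - h(a)
}

#' @export
print.exhaustion_estimate <- function(x, ...) {
  if (x$kind == "StEx") {
    cat(sprintf("<exhaustion_estimate> StEx = %.3f h after dawn (SE %.3g)%s\n",
                x$hours_after_dawn, x$se,
                if (isTRUE(x$degenerate)) " [degenerate: root precedes dusk]" else ""))
  } else {
    cat(sprintf("<exhaustion_estimate> StEx_app = %.3f h after dawn (95%% CI %.3f-%.3f, n = %d fits)\n",
                x$hours_after_dawn, x$ci95[1], x$ci95[2], x$n_fits))
  }
  invisible(x)
}
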