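# Small-sample corrected AIC; k counts mean parameters plus one for the
# residual variance.
aicc_from_rss <- function(n, rss, k) {
  if (n - k - 1 <= 0) return(Inf)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Wrap hours into [0, t_cycle).
wrap_zt <- function(zt, t_cycle) ((zt %% t_cycle) + t_cycle) %% t_cycle

# Circular mean of hours on a cycle of length t_cycle.
circular_mean_h <- function(h, t_cycle) {
  ang <- 2 * pi * h / t_cycle
  m <- atan2(mean(sin(ang)), mean(cos(ang)))
  wrap_zt(m * t_cycle / (2 * pi), t_cycle)
}

# Signed circular residual of h around center, in (-t_cycle/2, t_cycle/2].
circ_residual <- function(h, center, t_cycle) {
  d <- wrap_zt(h - center, t_cycle)
  ifelse(d > t_cycle / 2, d - t_cycle, d)
}

# Fit the best polynomial (degree 2-6) by AICc; returns a predict function
# or NULL if no degree is fittable.
best_poly_curve <- function(x, y) {
  n <- length(y)
  # center the time axis for numerical stability of the raw powers
  x0 <- mean(x)
  best_coef <- NULL; best_aicc <- Inf
  for (d in 2:6) {
    k <- d + 2  # coefficients + residual variance
    if (n - k - 1 <= 0) next
    X <- outer(x - x0, 0:d, `^`)
    fit <- stats::lm.fit(X, y)
    a <- aicc_from_rss(n, sum(fit$residuals^2), k)
    if (a < best_aicc - 1e-12) {  # ties resolved toward fewer parameters
      best_aicc <- a; best_coef <- fit$coefficients
    }
  }
  if (is.null(best_coef)) return(NULL)
  function(newx) {
    drop(outer(newx - x0, seq_along(best_coef) - 1, `^`) %*% best_coef)
  }
}

# Fit the best smoothing spline over a df grid by AICc.
best_spline_curve <- function(x, y, df_grid) {
  n <- length(y)
  best <- NULL; best_aicc <- Inf
  for (d in df_grid) {
    fit <- tryCatch(stats::smooth.spline(x, y, df = d),
                    error = function(e) NULL)
    if (is.null(fit)) next
    pred <- stats::predict(fit, x)$y
    a <- aicc_from_rss(n, sum((y - pred)^2), fit$df + 1)
    if (a < best_aicc - 1e-12) {
      best_aicc <- a; best <- fit
    }
  }
  if (is.null(best)) return(NULL)
  function(newx) stats::predict(best, newx)$y
}

# Locate the peak of a fitted curve on a fine grid; returns list(peak,
# monotone).
curve_peak <- function(curve_fn, lo, hi, step = 0.05) {
  grid <- seq(lo, hi, by = step)
  yy <- curve_fn(grid)
  d <- diff(yy)
  monotone <- all(d >= -1e-10) || all(d <= 1e-10)
  list(peak = grid[which.max(yy)], monotone = monotone)
}

#' Estimate the peak time of an oscillating transcript
#'
#' Bootstraps the replicate time series (resampling replicates within each
#' time point) and, for each draw, fits both a polynomial (degree 2-6) and
#' a smoothing spline (degrees-of-freedom grid), each selected by minimum
#' small-sample-corrected AIC (AICc), then records the ZT of the global
#' maximum of each selected curve. The reported peak time is the circular
#' mean of all per-draw peaks from both methods, with a bootstrap 95%
#' percentile CI on the circular residuals.
#'
#' To keep peaks near dawn interior to the fitting window, the series is
#' unwrapped onto a window starting at `unwrap_start` (default three
#' quarters of the cycle, i.e. ZT18 in a T24 cycle) and running one full
#' cycle: samples earlier than the start are shifted by one cycle length.
#'
#' If the selected curve is monotone over the window in more than half of
#' the draws, the oscillation is deemed too weak to score and the result
#' is flagged unscorable.
#'
#' @param data A single-series tidy transcript tibble with at least 5
#'   distinct ZTs and 2 replicates per ZT.
#' @param n_boot_per_method Bootstrap draws per method (50 each for the
#'   polynomial and spline routes by default).
#' @param seed Optional integer seed.
#' @param unwrap_start Window start, hours; `NULL` = 0.75 x cycle length.
#' @return An object of class `rhythm_feature` with `peak_zt` (hours,
#'   circular in `[0, cycle)`), `peak_ci95`, `scorable`, `n_peaks`,
#'   `method_peaks` (per-draw detail).
#' @export
peak_time <- function(data, n_boot_per_method = 50, seed = NULL,
                      unwrap_start = NULL) {
  one_series(data)
  regime <- regime_from_data(data)
  t_cycle <- regime$cycle_length_h
  if (is.null(unwrap_start)) unwrap_start <- 0.75 * t_cycle

  d <- dplyr::mutate(data, uzt = ifelse(.data$zt < unwrap_start - 1e-9,
                                        .data$zt + t_cycle, .data$zt))
  zts <- sort(unique(d$uzt))
  if (length(zts) < 5) {
    rlang::abort("need >= 5 distinct sampled time points",
                 class = "dielstarch_insufficient_data")
  }
  reps_per <- d |> dplyr::count(.data$uzt)
  if (any(reps_per$n < 2)) {
    rlang::abort("need >= 2 replicates per time point",
                 class = "dielstarch_insufficient_data")
  }
  vals_by_zt <- split(d$value, factor(d$uzt, levels = zts))
  df_grid <- seq(4, min(10, length(zts) - 1))

  one_draw <- function(method) {
    yb <- unlist(lapply(vals_by_zt, function(v)
      v[sample.int(length(v), replace = TRUE)]), use.names = FALSE)
    xb <- rep(zts, times = lengths(vals_by_zt))
    curve_fn <- if (method == "polynomial") best_poly_curve(xb, yb)
                else best_spline_curve(xb, yb, df_grid)
    if (is.null(curve_fn)) return(c(NA_real_, NA))
    pk <- curve_peak(curve_fn, min(zts), max(zts))
    c(pk$peak, pk$monotone)
  }
  run_all <- function() {
    purrr::map_dfr(c("polynomial", "spline"), function(m) {
      draws <- t(vapply(seq_len(n_boot_per_method), function(i) one_draw(m),
                        numeric(2)))
      tibble::tibble(method = m, peak_uzt = draws[, 1],
                     monotone = as.logical(draws[, 2]))
    })
  }
  draws <- if (is.null(seed)) run_all() else withr::with_seed(seed, run_all())
  n_total <- nrow(draws)
  frac_monotone <- mean(draws$monotone | is.na(draws$peak_uzt))
  usable <- dplyr::filter(draws, !.data$monotone, !is.na(.data$peak_uzt))

  if (frac_monotone > 0.5 || nrow(usable) == 0) {
    return(structure(
      list(peak_zt = NA_real_, peak_ci95 = c(lo = NA_real_, hi = NA_real_),
           scorable = FALSE, frac_monotone = frac_monotone,
           n_peaks = nrow(usable), method_peaks = draws,
           cycle_length_h = t_cycle),
      class = "rhythm_feature"
    ))
  }
  peaks <- wrap_zt(usable$peak_uzt, t_cycle)
  center <- circular_mean_h(peaks, t_cycle)
  res <- circ_residual(peaks, center, t_cycle)
  qs <- stats::quantile(res, c(0.025, 0.975), names = FALSE)
  structure(
    list(peak_zt = center,
         peak_ci95 = c(lo = wrap_zt(center + qs[1], t_cycle),
                       hi = wrap_zt(center + qs[2], t_cycle)),
         scorable = TRUE, frac_monotone = frac_monotone,
         n_peaks = nrow(usable), method_peaks = draws,
         cycle_length_h = t_cycle),
    class = "rhythm_feature"
  )
}

#' Estimate the amplitude of a diel oscillation
#'
#' Amplitude is the difference between the maximum and minimum mean level
#' over one cycle. Its standard error follows by Gaussian error
#' propagation from the SEMs of the two extreme time points,
#' `SE = sqrt(SEM_max^2 + SEM_min^2)`, and the 95% CI is a Student-t
#' interval on that SE.
#'
#' @param data A single-series tidy transcript tibble.
#' @return An object of class `rhythm_feature` with `amplitude`, `se`,
#'   `amplitude_ci95`, and the ZTs of the extremes.
#' @examples
#' s <- simulate_transcript(transcript_model(noise_sd = 0),
#'                          light_regime(24, 12))
#' amplitude(s)
#' @export
amplitude <- function(data) {
  one_series(data)
  regime <- regime_from_data(data)
  t_cycle <- regime$cycle_length_h
  # a dawn sample recorded at ZT cycle_length is the same phase as ZT0
  folded <- dplyr::mutate(data, zt = wrap_zt(.data$zt, t_cycle))
  prof <- mean_profile(folded, "dawn")
  if (nrow(prof) < 2) {
    rlang::abort("need at least two time points for an amplitude",
                 class = "dielstarch_insufficient_data")
  }
  i_max <- which.max(prof$mean); i_min <- which.min(prof$mean)
  amp <- prof$mean[i_max] - prof$mean[i_min]
  se <- sqrt(sum(c(prof$sem[i_max], prof$sem[i_min])^2, na.rm = TRUE))
  df <- prof$n[i_max] + prof$n[i_min] - 2
  tcrit <- stats::qt(0.975, df = max(df, 1))
  structure(
    list(amplitude = amp, se = se,
         amplitude_ci95 = c(lo = amp - tcrit * se, hi = amp + tcrit * se),
         zt_max = prof$offset[i_max], zt_min = prof$offset[i_min],
         cycle_length_h = t_cycle),
    class = "rhythm_feature"
  )
}

#' @export
print.rhythm_feature <- function(x, ...) {
  if (!is.null(x$peak_zt)) {
    if (isFALSE(x$scorable)) {
      cat("<rhythm_feature> no scorable peak (curve monotone in",
          sprintf("%.0f%%", 100 * x$frac_monotone), "of draws)\n")
    } else {
      cat(sprintf("<rhythm_feature> peak at ZT%.2f (95%% CI ZT%.2f-ZT%.2f, %d bootstrap peaks)\n",
                  x$peak_zt, x$peak_ci95[1], x$peak_ci95[2], x$n_peaks))
    }
  }
  if (!is.null(x$amplitude)) {
    cat(sprintf("<rhythm_feature> amplitude %.3f +/- %.3f (95%% CI %.3f-%.3f)\n",
                x$amplitude, x$se, x$amplitude_ci95[1], x$amplitude_ci95[2]))
  }
  invisible(x)
}
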