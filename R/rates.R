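#' Fit a linear rate to replicate diel data
#'
#' Estimates a rate as the slope of an ordinary least-squares line through
#' all replicate `(zt, value)` pairs in a closed ZT window — biological
#' replicates are never averaged before fitting, so the standard error
#' reflects replicate scatter. The 95% CI is `slope ± t(0.975, n-2) * SE`.
#' With `normalize = TRUE` every value is first divided by the series' mean
#' dusk value, giving a relative rate in fraction-of-dusk-starch per hour.
#'
#' @param data A single-series tidy diel tibble.
#' @param window Numeric `c(zt_start, zt_end)`; both endpoints are included
#'   (the dusk sample legitimately belongs to both the light-period and the
#'   night window).
#' @param normalize Divide by the mean dusk value before fitting?
#' @param dusk_zt ZT of dusk used for normalization; defaults to the
#'   regime's (effective) dusk.
#' @return An object of class `slope_fit`: slope, intercept (at ZT0),
#'   `se_slope`, `ci95`, `n_points`, the window, the underlying `lm` fit.
#' @examples
#' s <- simulate_starch(starch_model(noise_frac = 0), light_regime(24, 12))
#' fit_rate(s, window = c(12, 24))
#' @export
fit_rate <- function(data, window, normalize = FALSE, dusk_zt = NULL) {
  one_series(data)
  stopifnot(length(window) == 2, window[1] < window[2])
  regime <- regime_from_data(data)
  if (is.null(dusk_zt)) dusk_zt <- effective_dusk_zt(regime)

  sub <- dplyr::filter(data, .data$zt >= window[1] - 1e-9,
                       .data$zt <= window[2] + 1e-9)
  n_times <- dplyr::n_distinct(sub$zt)
  if (n_times < 3) {
    rlang::abort(
      sprintf("need >= 3 sampled time points in window [%g, %g], found %d",
              window[1], window[2], n_times),
      class = "dielstarch_insufficient_data"
    )
  }
  divisor <- 1
  if (normalize) {
    dusk_vals <- data$value[abs(data$zt - dusk_zt) < 1e-9]
    if (length(dusk_vals) == 0 || mean(dusk_vals) == 0) {
      rlang::abort("cannot normalize: no dusk samples or zero mean dusk value",
                   class = "dielstarch_degenerate_normalization")
    }
    divisor <- mean(dusk_vals)
  }
  sub <- dplyr::mutate(sub, .y = .data$value / divisor)
  fit <- stats::lm(.y ~ zt, data = sub)
  cf <- stats::coef(fit)
  se <- sqrt(diag(quiet_perfect_fit(stats::vcov(fit))))[["zt"]]
  n <- nrow(sub)
  tcrit <- stats::qt(0.975, df = n - 2)
  structure(
    list(slope = unname(cf[["zt"]]), intercept = unname(cf[["(Intercept)"]]),
         se_slope = se,
         ci95 = c(lo = cf[["zt"]] - tcrit * se, hi = cf[["zt"]] + tcrit * se),
         n_points = n, window = c(window[1], window[2]),
         normalized = normalize, divisor = divisor,
         unit = if (normalize) "fraction of dusk value per h"
                else paste0(sub$unit[1], " per h"),
         fit = fit, regime = regime),
    class = "slope_fit"
  )
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("<slope_fit> slope %.4g +/- %.3g (95%% CI %.4g to %.4g), n = %d, window ZT%g-ZT%g%s\n",
              x$slope, x$se_slope, x$ci95[1], x$ci95[2], x$n_points,
              x$window[1], x$window[2],
              if (x$normalized) ", dusk-normalized" else ""))
  invisible(x)
}

#' @rdname fit_rate
#' @details
#' `accumulation_rate()` fixes the window to the light period
#' `[0, photoperiod]`; `mobilization_rate()` to the night
#' `[photoperiod, cycle_length]`. For comparisons across T-cycles of
#' different night lengths, `cap_darkness_h` truncates the mobilization
#' window at `dusk + cap_darkness_h` (8.5 h caps every T-cycle's night at
#' the duration of a T17 night, so the initial mobilization rate is
#' compared over a common span of darkness).
#' @param ... Passed on to `fit_rate()`.
#' @export
accumulation_rate <- function(data, normalize = FALSE, ...) {
  regime <- regime_from_data(data)
  fit_rate(data, window = c(0, effective_dusk_zt(regime)),
           normalize = normalize, ...)
}

#' @rdname fit_rate
#' @param cap_darkness_h Optional cap on hours of darkness included in the
#'   mobilization window (e.g. 8.5 for cross-T-cycle comparisons).
#' @export
mobilization_rate <- function(data, normalize = FALSE, cap_darkness_h = NULL,
                              ...) {
  regime <- regime_from_data(data)
  dusk <- effective_dusk_zt(regime)
  end <- regime$cycle_length_h
  if (!is.null(cap_darkness_h)) end <- min(end, dusk + cap_darkness_h)
  fit_rate(data, window = c(dusk, end), normalize = normalize, ...)
}

#' Compare mobilization rates around a sudden early dusk
#'
#' Fits the three rate windows used to quantify the slowdown of starch
#' mobilization after an early dusk: the control night over all its time
#' points; the control restricted to time points where its starch content
#' is below the treated plants' content at darkening (so both fits cover a
#' comparable range of starch levels); and the treated plants' initial rate,
#' excluding time points once their starch falls below the control's dawn
#' level (where mobilization becomes visibly nonlinear). Content cutoffs
#' are resolved against time-point means, and time points are kept or
#' dropped whole.
#'
#' @param control Single-series tibble, unperturbed night.
#' @param treated Single-series tibble whose regime has an early-dusk
#'   perturbation.
#' @return A list of class `early_dusk_rates` with elements
#'   `control_full`, `control_matched`, `treated_initial` (each a
#'   [fit_rate()] result), `rate_ratio` (treated initial / control full)
#'   and `percent_decrease`.
#' @export
early_dusk_rate_windows <- function(control, treated) {
  regime_t <- regime_from_data(treated)
  if (regime_t$perturbation != "early_dusk") {
    rlang::abort("`treated` must carry an early-dusk perturbation",
                 class = "dielstarch_regime_error")
  }
  regime_c <- regime_from_data(control)
  dusk_c <- effective_dusk_zt(regime_c)
  dusk_t <- regime_t$early_dusk_zt
  t_end <- regime_c$cycle_length_h

  cmeans <- mean_profile(control, "dawn")
  tmeans <- mean_profile(treated, "dawn")
  treated_dusk_level <- tmeans$mean[which.min(abs(tmeans$offset - dusk_t))]
  control_dawn_level <- cmeans$mean[which.max(cmeans$offset)]

  control_full <- fit_rate(control, window = c(dusk_c, t_end))

  # control time points at or below the treated plants' content at darkening
  matched_zts <- cmeans$offset[cmeans$offset >= dusk_c &
                                 cmeans$mean <= treated_dusk_level + 1e-9]
  if (length(matched_zts) < 3) {
    rlang::abort("matched control window has fewer than 3 time points",
                 class = "dielstarch_insufficient_data"
    )
  }
  control_matched <- fit_rate(control,
                              window = range(matched_zts))

  # treated initial window: from early dusk until starch drops below the
  # control's dawn level
  night_t <- tmeans[tmeans$offset >= dusk_t, ]
  keep <- night_t$offset[night_t$mean >= control_dawn_level - 1e-9]
  if (length(keep) < 3) {
    rlang::abort("treated initial window has fewer than 3 time points",
                 class = "dielstarch_insufficient_data")
  }
  treated_initial <- fit_rate(treated, window = range(keep))

  ratio <- treated_initial$slope / control_full$slope
  structure(
    list(control_full = control_full, control_matched = control_matched,
         treated_initial = treated_initial,
         rate_ratio = ratio, percent_decrease = 100 * (1 - ratio)),
    class = "early_dusk_rates"
  )
}

#' Test for a difference in slopes between two series (ANCOVA)
#'
#' Pools the replicates of two series over a common ZT window and fits
#' `value ~ group * zt`; the group-by-time interaction tests whether the
#' two rates differ. Sums of squares are type III with sum-to-zero
#' contrasts, the convention for reporting genotype-by-time interactions in
#' diel time-course comparisons.
#'
#' @param a,b Single-series tibbles (e.g. two genotypes).
#' @param window ZT window `c(start, end)`, closed.
#' @param labels Length-2 character labels for the groups.
#' @return A list of class `slope_comparison`: `f_interaction`,
#'   `p_interaction`, `df`, the fitted `lm`, and the car::Anova table.
#' @export
compare_slopes <- function(a, b, window, labels = c("a", "b")) {
  one_series(a); one_series(b)
  pick <- function(d, g) {
    d |>
      dplyr::filter(.data$zt >= window[1] - 1e-9,
                    .data$zt <= window[2] + 1e-9) |>
      dplyr::transmute(group = g, zt = .data$zt, value = .data$value)
  }
  pooled <- dplyr::bind_rows(pick(a, labels[1]), pick(b, labels[2]))
  pooled$group <- factor(pooled$group)
  fit <- stats::lm(value ~ group * zt, data = pooled,
                   contrasts = list(group = "contr.sum"))
  if (stats::sigma(fit) < 1e-12) {
    an <- NULL
    ss_int <- sum((stats::fitted(fit) -
                     stats::fitted(stats::update(fit, . ~ group + zt)))^2)
    res <- list(f_interaction = NA_real_, p_interaction = NA_real_,
                ss_interaction = ss_int, degenerate = TRUE)
  } else {
    an <- car::Anova(fit, type = 3)
    row <- "group:zt"
    res <- list(f_interaction = an[row, "F value"],
                p_interaction = an[row, "Pr(>F)"],
                ss_interaction = an[row, "Sum Sq"], degenerate = FALSE)
  }
  structure(c(res, list(df = stats::df.residual(fit), fit = fit, anova = an,
                        window = window, labels = labels)),
            class = "slope_comparison")
}

#' @export
print.slope_comparison <- function(x, ...) {
  if (x$degenerate) {
    cat("<slope_comparison> zero residual variance; interaction SS =",
        format(x$ss_interaction), "(p undefined)\n")
  } else {
    cat(sprintf("<slope_comparison> interaction F = %.4g, p = %.3g %s\n",
                x$f_interaction, x$p_interaction, sig_stars(x$p_interaction)))
  }
  invisible(x)
}

#' Required mobilization-rate ratio after a dusk perturbation
#'
#' Under rate-setting by arithmetic division — mobilization rate R equals
#' dusk starch S divided by the time T remaining until anticipated dawn —
#' a perturbation that leaves a fraction `dusk_fraction` of the usual dusk
#' starch and changes the night from `night_base_h` to `night_new_h` hours
#' requires the new rate to be
#' `dusk_fraction * night_base_h / night_new_h` of the baseline rate for
#' starch still to run out exactly at dawn. E.g. a 4-h early dusk in a 12-h
#' photoperiod leaves 2/3 of the starch and stretches the night from 12 h
#' to 16 h, so the required rate is 0.5 of baseline: a 50% decrease.
#'
#' @param dusk_fraction Fraction of baseline dusk starch present (0, 1].
#' @param night_base_h,night_new_h Baseline and perturbed night lengths, h.
#' @return The required new/baseline rate ratio (a bare number).
#' @examples
#' required_rate_ratio(2 / 3, 12, 16) # 0.5
#' @export
required_rate_ratio <- function(dusk_fraction, night_base_h, night_new_h) {
  if (night_base_h <= 0 || night_new_h <= 0) {
    rlang::abort("night durations must be positive",
                 class = "dielstarch_validation_error")
  }
  dusk_fraction * night_base_h / night_new_h
}
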