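#' Describe a light regime
#'
#' A light regime defines the external light/dark cycle an experiment was run
#' in: the total cycle length (T-cycle), the photoperiod (hours of light,
#' dawn = ZT0, dusk = ZT `photoperiod_h`), the growth irradiance, and an
#' optional single-day perturbation applied on the harvest day.
#'
#' Zeitgeber time (ZT) is measured in decimal hours after the most recent
#' dawn throughout the package, so dawn is ZT0 and dusk is ZT
#' `photoperiod_h`. A dawn sample of the following cycle may be recorded at
#' ZT `cycle_length_h`.
#'
#' @param cycle_length_h Total duration of the external light-dark cycle in
#'   hours (e.g. 17, 24, 28).
#' @param photoperiod_h Hours of light per cycle; must satisfy
#'   `0 < photoperiod_h < cycle_length_h`.
#' @param irradiance Growth irradiance in µmol photons m⁻² s⁻¹.
#' @param perturbation One of `"none"`, `"early_dusk"` (lights off before the
#'   scheduled dusk), `"low_light_day"` (reduced irradiance for one light
#'   period), `"extended_night"`.
#' @param early_dusk_zt For `perturbation = "early_dusk"`: the ZT at which
#'   the lights were switched off; must be earlier than `photoperiod_h`.
#' @param low_light_irradiance For `perturbation = "low_light_day"`: the
#'   reduced irradiance, same units as `irradiance`.
#'
#' @return An object of class `light_regime` (a named list).
#' @examples
#' light_regime(24, 12, 160)
#' light_regime(24, 12, 160, perturbation = "early_dusk", early_dusk_zt = 8)
#' @export
light_regime <- function(cycle_length_h = 24, photoperiod_h = 12,
                         irradiance = 160,
                         perturbation = c("none", "early_dusk",
                                          "low_light_day", "extended_night"),
                         early_dusk_zt = NA_real_,
                         low_light_irradiance = NA_real_) {
  perturbation <- match.arg(perturbation)
  stopifnot(is.numeric(cycle_length_h), length(cycle_length_h) == 1L,
            is.numeric(photoperiod_h), length(photoperiod_h) == 1L)
  if (!(photoperiod_h > 0 && photoperiod_h < cycle_length_h)) {
    rlang::abort("`photoperiod_h` must lie strictly between 0 and `cycle_length_h`.",
                 class = "dielstarch_regime_error")
  }
  if (perturbation == "early_dusk") {
    if (!is.finite(early_dusk_zt) || early_dusk_zt <= 0 ||
        early_dusk_zt >= photoperiod_h) {
      rlang::abort("`early_dusk_zt` must lie in (0, photoperiod_h) for an early-dusk perturbation.",
                   class = "dielstarch_regime_error")
    }
  }
  if (perturbation == "low_light_day") {
    if (!is.finite(low_light_irradiance) || low_light_irradiance <= 0) {
      rlang::abort("`low_light_irradiance` must be a positive irradiance.",
                   class = "dielstarch_regime_error")
    }
  }
  structure(
    list(cycle_length_h = as.numeric(cycle_length_h),
         photoperiod_h = as.numeric(photoperiod_h),
         irradiance = as.numeric(irradiance),
         perturbation = perturbation,
         early_dusk_zt = as.numeric(early_dusk_zt),
         low_light_irradiance = as.numeric(low_light_irradiance)),
    class = "light_regime"
  )
}

#' @export
print.light_regime <- function(x, ...) {
  cat(sprintf("<light_regime> T%g cycle, %g h light / %g h dark, %g umol m-2 s-1",
              x$cycle_length_h, x$photoperiod_h,
              x$cycle_length_h - x$photoperiod_h, x$irradiance))
  if (x$perturbation != "none") {
    extra <- switch(x$perturbation,
                    early_dusk = sprintf(" (early dusk at ZT%g)", x$early_dusk_zt),
                    low_light_day = sprintf(" (low-light day, %g umol)", x$low_light_irradiance),
                    extended_night = " (extended night)")
    cat(extra)
  }
  cat("\n")
  invisible(x)
}

# Effective hours of light on the harvest day, honouring an early dusk.
effective_dusk_zt <- function(regime) {
  if (regime$perturbation == "early_dusk") regime$early_dusk_zt else regime$photoperiod_h
}

# Attach regime description to a tidy series table as columns.
regime_cols <- function(regime) {
  tibble::tibble(
    cycle_length_h = regime$cycle_length_h,
    photoperiod_h = regime$photoperiod_h,
    irradiance = regime$irradiance,
    perturbation = perturbation_label(regime)
  )
}

# Recover a light_regime from the columns of a single-series tibble.
# The `perturbation` column may carry a parameter after a colon, e.g.
# "early_dusk:8" or "low_light_day:90".
regime_from_data <- function(data) {
  for (col in c("cycle_length_h", "photoperiod_h")) {
    if (!col %in% names(data)) {
      rlang::abort(sprintf("column `%s` is required to recover the light regime", col),
                   class = "dielstarch_schema_error")
    }
  }
  pert_raw <- if ("perturbation" %in% names(data)) as.character(data$perturbation[1]) else "none"
  if (is.na(pert_raw) || pert_raw == "") pert_raw <- "none"
  parts <- strsplit(pert_raw, ":", fixed = TRUE)[[1]]
  pert <- parts[1]
  par <- if (length(parts) > 1) suppressWarnings(as.numeric(parts[2])) else NA_real_
  light_regime(
    cycle_length_h = data$cycle_length_h[1],
    photoperiod_h = data$photoperiod_h[1],
    irradiance = if ("irradiance" %in% names(data)) data$irradiance[1] else NA_real_,
    perturbation = pert,
    early_dusk_zt = if (pert == "early_dusk") par else NA_real_,
    low_light_irradiance = if (pert == "low_light_day") par else NA_real_
  )
}

# Serialize a regime's perturbation into the single TSV column.
perturbation_label <- function(regime) {
  switch(regime$perturbation,
         none = "none",
         early_dusk = sprintf("early_dusk:%g", regime$early_dusk_zt),
         low_light_day = sprintf("low_light_day:%g", regime$low_light_irradiance),
         extended_night = "extended_night")
}
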