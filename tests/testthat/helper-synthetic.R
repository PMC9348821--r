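# Builders for small deterministic fixtures used across the suite.

# A single-series tibble from explicit per-ZT replicate values.
# `values` is a named list: names are ZTs, elements are replicate vectors.
make_series <- function(values, regime = light_regime(24, 12),
                        genotype = "WT", variable = "starch",
                        unit = "umol_gFW", experiment_id = "toy") {
  rows <- purrr::imap_dfr(values, function(v, zt_chr) {
    tibble::tibble(zt = as.numeric(zt_chr), replicate = seq_along(v),
                   value = as.numeric(v))
  })
  dplyr::bind_cols(
    tibble::tibble(experiment_id = experiment_id, genotype = genotype,
                   cycle_length_h = regime$cycle_length_h,
                   photoperiod_h = regime$photoperiod_h,
                   irradiance = regime$irradiance,
                   perturbation = dielstarch:::perturbation_label(regime),
                   variable = variable, unit = unit),
    rows
  )[, c("experiment_id", "genotype", "cycle_length_h", "photoperiod_h",
        "irradiance", "perturbation", "zt", "variable", "unit",
        "replicate", "value")]
}

# Noiseless linear-night starch series: dusk value s_dusk at ZT `dusk`,
# reaching zero at ZT `exhaust`, sampled every `step` h (one replicate).
make_linear_night <- function(s_dusk = 12, dusk = 12, exhaust = 24,
                              t_cycle = 24, step = 2, n_reps = 1) {
  zts <- seq(dusk, t_cycle, by = step)
  vals <- pmax(0, s_dusk * (1 - (zts - dusk) / (exhaust - dusk)))
  day_zts <- seq(0, dusk - step, by = step)
  day_vals <- s_dusk * day_zts / dusk
  all_zts <- c(day_zts, zts)
  all_vals <- c(day_vals, vals)
  make_series(
    stats::setNames(lapply(all_vals, rep, n_reps), all_zts),
    regime = light_regime(t_cycle, dusk)
  )
}

# Closed-form least squares (normal equations), the independent OLS oracle.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  list(slope = slope, intercept = intercept,
       se_slope = sqrt(s2 / sxx))
}

# Raised-cosine transcript mean, written independently of the package.
bump_oracle <- function(zt, baseline, amp, peak, width, t_cycle) {
  d <- abs(zt - peak) %% t_cycle
  d <- pmin(d, t_cycle - d)
  baseline + amp * ifelse(d < width, (1 + cos(pi * d / width)) / 2, 0)
}
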