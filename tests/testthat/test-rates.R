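test_that("collinear night points give slope -1 with zero SE", {
  s <- make_linear_night(s_dusk = 12, dusk = 12, exhaust = 24)
  fit <- fit_rate(s, window = c(12, 24))
  expect_equal(fit$slope, -1)
  expect_equal(fit$se_slope, 0, tolerance = 1e-12)
  expect_equal(fit$n_points, 7)

  norm <- fit_rate(s, window = c(12, 24), normalize = TRUE)
  expect_equal(norm$slope, -1 / 12) # fraction of dusk starch per hour
})

test_that("fit_rate matches the closed-form least-squares oracle", {
  for (i in 1:20) {
    vals <- withr::with_seed(100 + i, {
      zts <- sort(sample(seq(12, 24, by = 2), 4))
      stats::setNames(lapply(zts, function(z) abs(rnorm(3, 10 - z / 3, 1))),
                      zts)
    })
    s <- make_series(vals)
    win <- range(as.numeric(names(vals)))
    fit <- fit_rate(s, window = win)
    oracle <- ols_oracle(s$zt[s$zt >= win[1] & s$zt <= win[2]],
                         s$value[s$zt >= win[1] & s$zt <= win[2]])
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-10)
    expect_equal(fit$se_slope, oracle$se_slope, tolerance = 1e-10)
  }
})

test_that("scaling values scales the absolute slope and leaves the relative one fixed", {
  s <- simulate_starch(starch_model(noise_frac = 0.05), light_regime(24, 12),
                       seed = 9)
  f1 <- mobilization_rate(s)
  n1 <- mobilization_rate(s, normalize = TRUE)
  s3 <- dplyr::mutate(s, value = value * 3)
  expect_equal(mobilization_rate(s3)$slope, 3 * f1$slope, tolerance = 1e-12)
  expect_equal(mobilization_rate(s3, normalize = TRUE)$slope, n1$slope,
               tolerance = 1e-12)
})

test_that("insufficient windows and degenerate normalization raise typed errors", {
  s <- make_linear_night()
  expect_error(fit_rate(s, window = c(12, 14)),
               class = "dielstarch_insufficient_data")
  zeroed <- dplyr::mutate(s, value = ifelse(zt == 12, 0, value))
  expect_error(fit_rate(zeroed, window = c(12, 24), normalize = TRUE),
               class = "dielstarch_degenerate_normalization")
})

test_that("accumulation and mobilization wrappers recover the generator's rates", {
  s <- simulate_starch(starch_model(accum_rate = 1, exhaustion_zt = 24,
                                    noise_frac = 0, n_reps = 1),
                       light_regime(24, 12))
  expect_equal(accumulation_rate(s)$slope, 1)
  expect_equal(mobilization_rate(s)$slope, -1)

  # exhaustion at dawn of a T28 cycle: the capped window is a subset of the
  # same linear segment, so capped and full-night slopes agree exactly
  s28 <- simulate_starch(starch_model(accum_rate = 1, exhaustion_zt = 28,
                                      noise_frac = 0, n_reps = 1),
                         light_regime(28, 14))
  expect_equal(mobilization_rate(s28, cap_darkness_h = 8.5)$slope,
               mobilization_rate(s28)$slope, tolerance = 1e-12)
  expect_equal(mobilization_rate(s28, cap_darkness_h = 8.5)$window, c(14, 22.5))
})

test_that("a photoperiod accumulation-rate contrast is recovered within its CI", {
  r12 <- light_regime(24, 12)
  r6 <- light_regime(24, 6)
  s12 <- simulate_starch(starch_model(accum_rate = 1, exhaustion_zt = 24,
                                      noise_frac = 0.05), r12, seed = 21)
  s6 <- simulate_starch(starch_model(accum_rate = 1.85, exhaustion_zt = 24,
                                     noise_frac = 0.05), r6, seed = 22)
  a12 <- accumulation_rate(s12)
  a6 <- accumulation_rate(s6)
  ratio <- a6$slope / a12$slope
  # delta-method CI half-width on the ratio
  se_ratio <- ratio * sqrt((a6$se_slope / a6$slope)^2 +
                             (a12$se_slope / a12$slope)^2)
  expect_lt(abs(ratio - 1.85), 2 * se_ratio + 0.05)
})

test_that("early-dusk rate windows reproduce the halved-rate geometry", {
  control <- make_linear_night(s_dusk = 12, dusk = 12, exhaust = 24)
  r_ed <- light_regime(24, 12, 160, "early_dusk", early_dusk_zt = 8)
  zts <- seq(8, 24, by = 2)
  treated <- make_series(
    stats::setNames(as.list(pmax(0, 8 - 0.5 * (zts - 8))), zts),
    regime = r_ed)
  res <- early_dusk_rate_windows(control, treated)
  expect_equal(res$control_full$slope, -1)
  expect_equal(res$treated_initial$slope, -0.5)
  expect_equal(res$rate_ratio, 0.5)
  expect_equal(res$percent_decrease, 50)
  # matched control window starts where control content reaches the
  # treated plants' content at darkening (8 at ZT16)
  expect_equal(res$control_matched$window, c(16, 24))
})

test_that("a truncated day with an unchanged rate yields a ratio near one", {
  # control dawn content 3 so the treated cutoff bites before the clip at 0
  control <- make_linear_night(s_dusk = 12, dusk = 12, exhaust = 28)
  r_ed <- light_regime(24, 12, 160, "early_dusk", early_dusk_zt = 8)
  zts <- seq(8, 24, by = 2)
  treated <- make_series(
    stats::setNames(as.list(pmax(0, 8 - 0.75 * (zts - 8))), zts),
    regime = r_ed)
  res <- early_dusk_rate_windows(control, treated)
  expect_equal(res$control_full$slope, -0.75)
  expect_equal(res$treated_initial$slope, -0.75)
  expect_equal(res$rate_ratio, 1)
})

test_that("a simulated 15% slowdown is recovered from the window analysis", {
  control <- make_linear_night(s_dusk = 12, dusk = 12, exhaust = 26)
  rate_c <- -12 / 14
  r_ed <- light_regime(24, 12, 160, "early_dusk", early_dusk_zt = 8)
  zts <- seq(8, 24, by = 2)
  treated <- make_series(
    stats::setNames(as.list(pmax(0, 8 + 0.85 * rate_c * (zts - 8))), zts),
    regime = r_ed)
  res <- early_dusk_rate_windows(control, treated)
  expect_equal(res$percent_decrease, 15, tolerance = 1e-6)
})

test_that("identical groups give zero interaction sum of squares", {
  s <- simulate_starch(starch_model(), light_regime(24, 12), seed = 31)
  cmp <- compare_slopes(s, dplyr::mutate(s, genotype = "copy"),
                        window = c(12, 24))
  expect_true(cmp$degenerate || cmp$ss_interaction < 1e-20)
  expect_lt(cmp$ss_interaction, 1e-20)
})

test_that("clearly different slopes are detected at p < 1e-6", {
  a <- simulate_starch(starch_model(accum_rate = 1, exhaustion_zt = 24,
                                    noise_frac = 0.01), light_regime(24, 12),
                       seed = 41)
  b <- simulate_starch(starch_model(accum_rate = 1, exhaustion_zt = 36,
                                    noise_frac = 0.01), light_regime(24, 12),
                       seed = 42)
  cmp <- compare_slopes(a, b, window = c(12, 24))
  expect_lt(cmp$p_interaction, 1e-6)
})

test_that("the slope-interaction test holds its size under the null", {
  # equal slopes, different intercepts; type-I rate should be ~5%
  n_sim <- 300
  rejections <- withr::with_seed(77, {
    sum(vapply(seq_len(n_sim), function(i) {
      zts <- seq(12, 24, by = 4)
      a <- make_series(stats::setNames(
        lapply(zts, function(z) 12 - z / 2 + rnorm(3, 0, 0.5)), zts),
        genotype = "A")
      b <- make_series(stats::setNames(
        lapply(zts, function(z) 15 - z / 2 + rnorm(3, 0, 0.5)), zts),
        genotype = "B")
      compare_slopes(a, b, window = c(12, 24))$p_interaction < 0.05
    }, logical(1)))
  })
  expect_gt(rejections / n_sim, 0.02)
  expect_lt(rejections / n_sim, 0.09)
})

test_that("required-rate arithmetic follows R = S/T", {
  expect_equal(required_rate_ratio(2 / 3, 12, 16), 0.5)
  expect_equal(required_rate_ratio(1, 12, 12), 1)
  expect_equal(required_rate_ratio(0.5, 12, 18), 1 / 3)
  expect_error(required_rate_ratio(0.5, 0, 12),
               class = "dielstarch_validation_error")
})
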