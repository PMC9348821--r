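test_that("a clean symmetric bump peaks where it was planted", {
  r <- light_regime(24, 12)
  s <- simulate_transcript(transcript_model(peak_zt = 4, noise_sd = 0.01,
                                            n_reps = 3), r, seed = 1)
  pt <- peak_time(s, seed = 2)
  expect_true(pt$scorable)
  expect_lt(abs(pt$peak_zt - 4), 0.5)
})

test_that("wrap-around peaks near dawn are recovered within an hour", {
  r <- light_regime(24, 12)
  s <- simulate_transcript(transcript_model(peak_zt = 22.3, amplitude = 3,
                                            noise_sd = 0.3, n_reps = 3),
                           r, seed = 11)
  pt <- peak_time(s, seed = 12)
  expect_true(pt$scorable)
  d <- abs(pt$peak_zt - 22.3) %% 24
  expect_lt(min(d, 24 - d), 1)
})

test_that("polynomial and spline routes agree on noiseless bumps", {
  r <- light_regime(24, 12)
  for (w in c(4, 6, 8)) {
    s <- simulate_transcript(transcript_model(peak_zt = 6, peak_width = w,
                                              noise_sd = 0.01, n_reps = 2),
                             r, seed = 20 + w)
    pt <- peak_time(s, n_boot_per_method = 20, seed = 30 + w)
    by_method <- tapply(
      dielstarch:::wrap_zt(pt$method_peaks$peak_uzt, 24),
      pt$method_peaks$method, median, na.rm = TRUE)
    expect_lt(abs(by_method[["polynomial"]] - by_method[["spline"]]), 1)
  }
})

test_that("flat series are declared unscorable rather than scored", {
  r <- light_regime(24, 12)
  s <- simulate_transcript(transcript_model(amplitude = 0, noise_sd = 0.05,
                                            n_reps = 3), r, seed = 40)
  pt <- peak_time(s, seed = 41)
  if (!pt$scorable) {
    expect_true(is.na(pt$peak_zt))
  } else {
    # pure noise can fit a wiggly curve; the CI must then be very wide
    expect_gt(diff(range(dielstarch:::circ_residual(
      dielstarch:::wrap_zt(pt$method_peaks$peak_uzt[
        !pt$method_peaks$monotone &
          !is.na(pt$method_peaks$peak_uzt)], 24),
      pt$peak_zt, 24))), 4)
  }
})

test_that("amplitude follows the max-minus-min rule with propagated error", {
  # means {2, 3, 7, 5}, SEMs {0.3, 0.3, 0.4, 0.3} via symmetric duplicates
  s <- make_series(list(`0` = c(1.7, 2.3), `6` = c(2.7, 3.3),
                        `12` = c(6.6, 7.4), `18` = c(4.7, 5.3)),
                   variable = "transcript:G",
                   unit = "log2_copies_per_2.5e7_gFW")
  am <- amplitude(s)
  expect_equal(am$amplitude, 5)
  expect_equal(am$se, sqrt(0.4^2 + 0.3^2))
  expect_equal(am$zt_max, 12)
  expect_equal(am$zt_min, 0)
})

test_that("constant series have zero amplitude", {
  s <- make_series(list(`0` = c(5, 5), `6` = c(5, 5), `12` = c(5, 5)),
                   variable = "transcript:G",
                   unit = "log2_copies_per_2.5e7_gFW")
  expect_equal(amplitude(s)$amplitude, 0)
})

test_that("amplitude is shift-invariant and the peak survives affine transforms", {
  r <- light_regime(24, 12)
  s <- simulate_transcript(transcript_model(peak_zt = 8, noise_sd = 0.2,
                                            n_reps = 3), r, seed = 50)
  am <- amplitude(s)
  am_shift <- amplitude(dplyr::mutate(s, value = value + 100))
  expect_equal(am$amplitude, am_shift$amplitude, tolerance = 1e-12)

  pt <- peak_time(s, seed = 51)
  pt_affine <- peak_time(dplyr::mutate(s, value = 3 * value + 100),
                         seed = 51)
  expect_equal(pt$peak_zt, pt_affine$peak_zt, tolerance = 0.2)
})

test_that("halved damping halves the amplitude", {
  r <- light_regime(24, 12)
  full <- simulate_transcript(transcript_model(damping = 1, noise_sd = 0,
                                               n_reps = 2), r, seed = 1)
  half <- simulate_transcript(transcript_model(damping = 0.5, noise_sd = 0,
                                               n_reps = 2), r, seed = 1)
  expect_equal(amplitude(half)$amplitude / amplitude(full)$amplitude, 0.5)
})

test_that("peak recovery error stays within an hour in the median", {
  errs <- vapply(1:20, function(seed) {
    s <- simulate_transcript(transcript_model(amplitude = 3, peak_zt = 5,
                                              noise_sd = 0.3, n_reps = 3),
                             light_regime(24, 12), seed = seed)
    pt <- peak_time(s, n_boot_per_method = 25, seed = 1000 + seed)
    if (!pt$scorable) return(NA_real_)
    d <- abs(pt$peak_zt - 5) %% 24
    min(d, 24 - d)
  }, numeric(1))
  expect_lte(stats::median(errs, na.rm = TRUE), 1)
})

test_that("too few time points or replicates raise typed errors", {
  s <- make_series(list(`0` = c(1, 2), `6` = c(2, 3), `12` = c(3, 4)),
                   variable = "transcript:G",
                   unit = "log2_copies_per_2.5e7_gFW")
  expect_error(peak_time(s), class = "dielstarch_insufficient_data")
  single_rep <- make_series(list(`0` = 1, `4` = 2, `8` = 3, `12` = 2,
                                 `16` = 1, `20` = 1),
                            variable = "transcript:G",
                            unit = "log2_copies_per_2.5e7_gFW")
  expect_error(peak_time(single_rep),
               class = "dielstarch_insufficient_data")
})
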