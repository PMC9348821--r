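make_profile <- function(offsets, means, sems) {
  tibble::tibble(offset = offsets, mean = means, sem = sems,
                 n = rep(3L, length(offsets)))
}

test_that("identical profiles have zero distance", {
  p <- make_profile(c(0, 4, 8, 12), c(1, 3, 2, 1), rep(0.2, 4))
  pd <- pairwise_dist(p, p)
  expect_equal(pd$dist, 0)
})

test_that("a constant offset gives the closed-form distance", {
  a <- make_profile(c(0, 4, 8, 12), c(1, 3, 2, 1), rep(0, 4))
  b <- make_profile(c(0, 4, 8, 12), c(3, 5, 4, 3), rep(0, 4))
  expect_warning(pd <- pairwise_dist(a, b), "NORM is infinite")
  expect_equal(pd$dist, 2 * sqrt(4)) # delta = 2 at k = 4 points
  expect_true(is.infinite(pd$norm))
})

test_that("the propagated error matches a numeric-Jacobian oracle", {
  for (i in 1:10) {
    vals <- withr::with_seed(200 + i, {
      list(ma = runif(5, 1, 10), mb = runif(5, 1, 10),
           sa = runif(5, 0.1, 0.5), sb = runif(5, 0.1, 0.5))
    })
    offs <- c(0, 3, 6, 9, 12)
    a <- make_profile(offs, vals$ma, vals$sa)
    b <- make_profile(offs, vals$mb, vals$sb)
    pd <- pairwise_dist(a, b)

    dist_of <- function(ma, mb) sqrt(sum((ma - mb)^2))
    h <- 1e-6
    grad_a <- vapply(1:5, function(j) {
      ma2 <- vals$ma; ma2[j] <- ma2[j] + h
      (dist_of(ma2, vals$mb) - dist_of(vals$ma, vals$mb)) / h
    }, numeric(1))
    grad_b <- vapply(1:5, function(j) {
      mb2 <- vals$mb; mb2[j] <- mb2[j] + h
      (dist_of(vals$ma, mb2) - dist_of(vals$ma, vals$mb)) / h
    }, numeric(1))
    oracle_err <- sqrt(sum(grad_a^2 * vals$sa^2) + sum(grad_b^2 * vals$sb^2))
    expect_equal(pd$propagated_error, oracle_err, tolerance = 1e-5)
  }
})

test_that("pairwise distance is symmetric and satisfies the triangle inequality", {
  offs <- c(0, 3, 6, 9)
  withr::with_seed(9, {
    a <- make_profile(offs, runif(4, 1, 5), runif(4, 0.1, 0.3))
    b <- make_profile(offs, runif(4, 1, 5), runif(4, 0.1, 0.3))
    cc <- make_profile(offs, runif(4, 1, 5), runif(4, 0.1, 0.3))
  })
  expect_equal(pairwise_dist(a, b)$dist, pairwise_dist(b, a)$dist)
  expect_lte(pairwise_dist(a, cc)$dist,
             pairwise_dist(a, b)$dist + pairwise_dist(b, cc)$dist + 1e-12)
})

# Simulate one transcript across three photoperiods, phase-locked to dawn
# or dusk.
locked_set <- function(lock = c("dawn", "dusk"), seed = 1, noise_sd = 0.2,
                       gene = "G1") {
  lock <- match.arg(lock)
  purrr::map_dfr(c(6, 12, 18), function(p) {
    r <- light_regime(24, p)
    peak <- if (lock == "dawn") 3 else dielstarch:::wrap_zt(p + 3, 24)
    simulate_transcript(
      transcript_model(peak_zt = peak, amplitude = 4, noise_sd = noise_sd,
                       n_reps = 3),
      r, gene = gene, seed = seed + p)
  })
}

test_that("dawn-locked transcripts align better on a dawn axis and vice versa", {
  dawn_locked <- locked_set("dawn", seed = 100)
  expect_lt(alignment_scores(dawn_locked, "dawn")$dist_raw,
            alignment_scores(dawn_locked, "dusk")$dist_raw)
  dusk_locked <- locked_set("dusk", seed = 200)
  expect_gt(alignment_scores(dusk_locked, "dawn")$dist_raw,
            alignment_scores(dusk_locked, "dusk")$dist_raw)
})

test_that("identical treatments give zero distance under both anchors", {
  r6 <- light_regime(24, 6)
  s <- simulate_transcript(transcript_model(noise_sd = 0), r6, seed = 1)
  twin <- dplyr::mutate(s, genotype = "twin")
  both <- dplyr::bind_rows(s, twin)
  expect_equal(alignment_scores(both, "dawn")$dist_raw, 0, tolerance = 1e-12)
  expect_equal(alignment_scores(both, "dusk")$dist_raw, 0, tolerance = 1e-12)
})

test_that("min-max scaling maps the observed extremes to 0 and 1, order preserved", {
  scores <- tibble::tibble(
    transcript = rep(c("G1", "G2", "G3"), each = 2),
    anchor = rep(c("dawn", "dusk"), 3),
    dist_raw = c(1, 5, 2, 4, 0.5, 3),
    norm_raw = c(10, 50, 20, 40, 5, 30)
  )
  scaled <- scale_alignment_scores(scores)
  expect_equal(min(scaled$dist_scaled), 0)
  expect_equal(max(scaled$dist_scaled), 1)
  expect_equal(order(scaled$dist_scaled), order(scaled$dist_raw))
  expect_equal(order(scaled$norm_scaled), order(scaled$norm_raw))
})

test_that("relabeled identical series produce no photoperiod effect", {
  r6 <- light_regime(24, 6)
  s <- simulate_transcript(transcript_model(noise_sd = 0.2), r6, seed = 7)
  twin <- dplyr::mutate(s, genotype = "twin")
  res <- alignment_anova(dplyr::bind_rows(s, twin), "dawn",
                         treatment = "genotype")
  expect_equal(res$p_treatment, 1, tolerance = 1e-6)
  expect_true(res$aligned)
})

test_that("dawn-locked series pass the dawn test and fail the dusk test", {
  d <- locked_set("dawn", seed = 300, noise_sd = 0.25)
  two <- dplyr::filter(d, photoperiod_h %in% c(6, 18))
  dawn <- alignment_anova(two, "dawn")
  dusk <- alignment_anova(two, "dusk")
  # a time-shifted profile keeps its average level, so desynchronization
  # surfaces in the photoperiod-by-offset interaction
  expect_true(dawn$aligned)
  expect_lt(dusk$p_interaction, 0.05)
  expect_false(dusk$aligned)
})
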