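# Interpolate two aligned profiles onto the intersection of their offset
# ranges at the finest common sampling step; returns a tibble with both
# means and sems on the shared grid.
shared_grid_profiles <- function(a, b) {
  lo <- max(min(a$offset), min(b$offset))
  hi <- min(max(a$offset), max(b$offset))
  if (hi <= lo) {
    rlang::abort("profiles have no overlapping offset range",
                 class = "dielstarch_alignment_error")
  }
  step <- min(min(diff(sort(unique(a$offset)))),
              min(diff(sort(unique(b$offset)))))
  grid <- seq(lo, hi, by = step)
  interp <- function(p, what) {
    stats::approx(p$offset, p[[what]], xout = grid, rule = 1)$y
  }
  tibble::tibble(
    offset = grid,
    a_mean = interp(a, "mean"), b_mean = interp(b, "mean"),
    a_sem = interp(a, "sem"), b_sem = interp(b, "sem")
  )
}

#' Euclidean distance between two aligned profiles (DIST/NORM)
#'
#' Interpolates both profiles onto their shared offset grid and computes
#' the Euclidean distance `dist = sqrt(sum_j (a_j - b_j)^2)` between the
#' mean trajectories, together with its first-order (Gaussian) propagated
#' error `sqrt(sum_j (a_j - b_j)^2 (sem_aj^2 + sem_bj^2)) / dist` and the
#' signal-to-noise style ratio `norm = dist / propagated_error`. A small
#' DIST means the two treatments trace the same profile on this time base;
#' NORM expresses the same distance in units of its own uncertainty.
#'
#' @param a,b Aligned profiles from [mean_profile()] (columns `offset`,
#'   `mean`, `sem`).
#' @return A list with `dist`, `propagated_error`, `norm`, `n_offsets`,
#'   and the shared grid tibble.
#' @export
pairwise_dist <- function(a, b) {
  g <- shared_grid_profiles(a, b)
  if (nrow(g) < 3) {
    rlang::abort("need >= 3 shared offsets to compare profiles",
                 class = "dielstarch_alignment_error")
  }
  diffs <- g$a_mean - g$b_mean
  dist <- sqrt(sum(diffs^2))
  var_terms <- diffs^2 * (dplyr::coalesce(g$a_sem, 0)^2 +
                            dplyr::coalesce(g$b_sem, 0)^2)
  if (dist == 0) {
    err <- 0
    norm <- 0
  } else {
    err <- sqrt(sum(var_terms)) / dist
    if (err == 0) {
      rlang::warn("zero propagated error with nonzero distance; NORM is infinite")
      norm <- Inf
    } else {
      norm <- dist / err
    }
  }
  list(dist = dist, propagated_error = err, norm = norm,
       n_offsets = nrow(g), grid = g)
}

#' Score dawn- or dusk-anchored alignment of one transcript across treatments
#'
#' Aggregates the pairwise profile distances between all treatments
#' (photoperiods, or control vs perturbation) after anchoring every series
#' to dawn or to dusk. The raw DIST score is the arithmetic mean of all
#' pairwise Euclidean distances on the shared grid; the raw NORM score is
#' the mean of the error-normalized distances. Computed once per anchor,
#' these tell whether the treatments' profiles superimpose better on a
#' time-since-dawn or a time-since-dusk axis.
#'
#' @param data Tidy tibble holding one variable measured in >= 2
#'   treatments (series distinguished by regime columns).
#' @param anchor `"dawn"` or `"dusk"`.
#' @return A list of class `alignment_score`: `anchor`, `dist_raw`,
#'   `norm_raw`, `n_pairs`, per-pair detail tibble.
#' @export
alignment_scores <- function(data, anchor = c("dawn", "dusk")) {
  anchor <- match.arg(anchor)
  series <- split_series(data)
  if (length(series) < 2) {
    rlang::abort("need >= 2 treatments to score alignment",
                 class = "dielstarch_alignment_error")
  }
  profiles <- lapply(series, mean_profile, anchor = anchor)
  pairs <- utils::combn(length(profiles), 2)
  detail <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    pd <- pairwise_dist(profiles[[i1]], profiles[[i2]])
    tibble::tibble(treatment_a = names(profiles)[i1],
                   treatment_b = names(profiles)[i2],
                   dist = pd$dist, norm = pd$norm,
                   n_offsets = pd$n_offsets)
  })
  structure(
    list(anchor = anchor, dist_raw = mean(detail$dist),
         norm_raw = mean(detail$norm), n_pairs = nrow(detail),
         pairs = detail),
    class = "alignment_score"
  )
}

#' @export
print.alignment_score <- function(x, ...) {
  cat(sprintf("<alignment_score> %s-anchored: DIST = %.4g, NORM = %.4g (%d pairs)\n",
              x$anchor, x$dist_raw, x$norm_raw, x$n_pairs))
  invisible(x)
}

#' Min-max scale alignment scores across an experiment
#'
#' Rescales each score type independently to `[0, 1]` across the full set
#' of (transcript x genotype x anchor) scores of one analysis run, so 0
#' marks the best and 1 the worst alignment observed in that run.
#'
#' @param scores A tibble with columns `dist_raw` and `norm_raw` (one row
#'   per transcript x anchor, e.g. built from [alignment_scores()]
#'   results).
#' @return The tibble with `dist_scaled` and `norm_scaled` columns added.
#' @export
scale_alignment_scores <- function(scores) {
  minmax <- function(v) {
    rng <- range(v, finite = TRUE)
    if (diff(rng) == 0) return(rep(0, length(v)))
    (v - rng[1]) / diff(rng)
  }
  dplyr::mutate(scores,
                dist_scaled = minmax(.data$dist_raw),
                norm_scaled = minmax(.data$norm_raw))
}

#' Two-way ANOVA test of treatment alignment
#'
#' Tests whether series from two (or more) treatments are significantly
#' different once aligned to the chosen anchor: replicate-level model
#' `value ~ treatment * offset` with offset categorical on the shared
#' sampling grid, type II sums of squares. Non-significant treatment main
#' effect and interaction at `alpha` mean the series are statistically
#' indistinguishable on that time base ("aligned").
#'
#' @param data Tidy tibble holding one variable in >= 2 treatments.
#' @param anchor `"dawn"` or `"dusk"`.
#' @param treatment Column distinguishing treatments; default
#'   `"photoperiod_h"`.
#' @param alpha Significance level for the `aligned` verdict.
#' @return A list of class `alignment_anova`: `p_treatment`,
#'   `p_interaction`, `aligned`, the fit and the type II table.
#' @export
alignment_anova <- function(data, anchor = c("dawn", "dusk"),
                            treatment = "photoperiod_h", alpha = 0.05) {
  anchor <- match.arg(anchor)
  series <- split_series(data)
  if (length(series) < 2) {
    rlang::abort("need >= 2 treatments", class = "dielstarch_alignment_error")
  }
  rows <- purrr::map_dfr(series, function(s) {
    regime <- regime_from_data(s)
    p <- regime$photoperiod_h; tt <- regime$cycle_length_h
    s |>
      dplyr::mutate(offset = if (anchor == "dawn") .data$zt
                    else ifelse(.data$zt >= p, .data$zt - p,
                                .data$zt + (tt - p))) |>
      dplyr::transmute(treatment = as.character(.data[[treatment]]),
                       offset = .data$offset, value = .data$value)
  })
  # restrict to the offsets every treatment sampled (shared grid)
  shared <- rows |>
    dplyr::distinct(.data$treatment, .data$offset) |>
    dplyr::count(.data$offset) |>
    dplyr::filter(.data$n == dplyr::n_distinct(rows$treatment)) |>
    dplyr::pull(.data$offset)
  if (length(shared) < 3) {
    rlang::abort("fewer than 3 offsets shared by all treatments",
                 class = "dielstarch_alignment_error")
  }
  rows <- dplyr::filter(rows, .data$offset %in% shared)
  cells <- table(rows$treatment, rows$offset)
  if (any(cells == 0)) {
    rlang::warn("empty treatment x offset cell(s); type II SS still estimable")
  }
  d <- tibble::tibble(value = rows$value,
                      treatment = factor(rows$treatment),
                      offset = factor(rows$offset))
  fit <- stats::lm(value ~ treatment * offset, data = d)
  an <- car::Anova(fit, type = 2)
  p_tr <- an["treatment", "Pr(>F)"]
  p_int <- an["treatment:offset", "Pr(>F)"]
  structure(
    list(anchor = anchor, p_treatment = p_tr, p_interaction = p_int,
         aligned = (is.na(p_tr) || p_tr >= alpha) &&
           (is.na(p_int) || p_int >= alpha),
         fit = fit, anova = an, n_offsets = length(shared)),
    class = "alignment_anova"
  )
}

#' @export
print.alignment_anova <- function(x, ...) {
  cat(sprintf("<alignment_anova> %s-anchored: p(treatment) = %.3g, p(interaction) = %.3g -> %s\n",
              x$anchor, x$p_treatment, x$p_interaction,
              if (x$aligned) "aligned" else "desynchronized"))
  invisible(x)
}
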