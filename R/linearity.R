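#' Score deviation of night-time starch mobilization from linearity
#'
#' Interpolates a straight reference line (chord) between the mean dusk and
#' mean dawn starch contents; at each interior night time point the residue
#' `(observed mean - predicted) / predicted` measures relative deviation
#' from linear mobilization, and the score is the mean of these normalized
#' residues. The score is zero for linear mobilization, negative when
#' starch is mobilized too fast early in the night (content dips below the
#' chord), and positive when initial mobilization is too slow. The 95% CI
#' is a nonparametric percentile bootstrap: replicate values are resampled
#' with replacement within every time point — including the dusk and dawn
#' endpoints, which re-anchor the chord in each draw.
#'
#' The average runs over all time points by default; since the dusk and
#' dawn endpoint residues are identically zero by construction, this
#' amounts to dividing the interior residue sum by the total number of
#' time points. `include_endpoints = FALSE` averages over the interior
#' points only, which rescales the score by (n interior + 2)/(n interior)
#' and makes it a pure summary of interior shape.
#'
#' @param data A single-series tidy starch tibble covering dusk to dawn.
#' @param n_boot Bootstrap draws for the CI; 0 skips the bootstrap.
#' @param seed Optional integer seed for the bootstrap.
#' @param include_endpoints Count the (zero) endpoint residues in the
#'   mean? Default `TRUE`.
#' @return An object of class `nonlinearity_result`: `score`, `ci95`,
#'   `n_interior_points`, `per_point_residues` (tibble of zt, observed,
#'   predicted, residue), `n_boot`, `seed`.
#' @examples
#' s <- simulate_starch(starch_model(curvature = 2, noise_frac = 0),
#'                      light_regime(24, 12))
#' nonlinearity(s, n_boot = 0)
#' @export
nonlinearity <- function(data, n_boot = 1000, seed = NULL,
                         include_endpoints = TRUE) {
  one_series(data)
  regime <- regime_from_data(data)
  dusk <- effective_dusk_zt(regime)
  dawn <- regime$cycle_length_h

  night <- dplyr::filter(data, .data$zt >= dusk - 1e-9,
                         .data$zt <= dawn + 1e-9)
  zts <- sort(unique(night$zt))
  if (!any(abs(zts - dusk) < 1e-9) || !any(abs(zts - dawn) < 1e-9)) {
    rlang::abort("dusk and dawn reference time points are required",
                 class = "dielstarch_insufficient_data")
  }
  interior <- zts[zts > dusk + 1e-9 & zts < dawn - 1e-9]
  if (length(interior) < 1) {
    rlang::abort("need at least one interior night time point",
                 class = "dielstarch_insufficient_data")
  }
  vals_by_zt <- split(night$value, factor(night$zt, levels = zts))

  score_of <- function(vals) {
    means <- vapply(vals, mean, numeric(1))
    m_dusk <- means[[which(abs(zts - dusk) < 1e-9)]]
    m_dawn <- means[[which(abs(zts - dawn) < 1e-9)]]
    if (!(m_dusk > m_dawn && m_dawn >= 0)) {
      return(list(score = NA_real_, residues = NULL))
    }
    pred <- m_dusk + (m_dawn - m_dusk) * (interior - dusk) / (dawn - dusk)
    obs <- unname(means[match(interior, zts)])
    ok <- pred > 0
    if (!all(ok)) {
      rlang::warn("interior point(s) with non-positive predicted content excluded")
    }
    residues <- (obs[ok] - pred[ok]) / pred[ok]
    denom <- if (include_endpoints) sum(ok) + 2 else sum(ok)
    list(score = sum(residues) / denom,
         residues = tibble::tibble(zt = interior[ok], observed = obs[ok],
                                   predicted = pred[ok], residue = residues))
  }

  point <- score_of(vals_by_zt)
  if (is.na(point$score)) {
    rlang::abort("dusk mean must exceed dawn mean (>= 0) to anchor the chord",
                 class = "dielstarch_degenerate_reference")
  }

  ci <- c(lo = NA_real_, hi = NA_real_)
  boot_scores <- NULL
  if (n_boot > 0) {
    run_boot <- function() {
      vapply(seq_len(n_boot), function(i) {
        res <- score_of(lapply(vals_by_zt, function(v)
          v[sample.int(length(v), replace = TRUE)]))
        res$score
      }, numeric(1))
    }
    boot_scores <- if (is.null(seed)) run_boot()
                   else withr::with_seed(seed, run_boot())
    qs <- stats::quantile(boot_scores, c(0.025, 0.975), na.rm = TRUE,
                          names = FALSE)
    ci <- c(lo = qs[1], hi = qs[2])
  }
  structure(
    list(score = point$score, ci95 = ci,
         n_interior_points = nrow(point$residues),
         per_point_residues = point$residues,
         boot_scores = boot_scores, n_boot = n_boot, seed = seed,
         include_endpoints = include_endpoints),
    class = "nonlinearity_result"
  )
}

#' @export
print.nonlinearity_result <- function(x, ...) {
  cat(sprintf("<nonlinearity_result> score = %.4f", x$score))
  if (!is.na(x$ci95[1])) {
    cat(sprintf(" (95%% CI %.4f to %.4f, %d bootstrap draws)",
                x$ci95[1], x$ci95[2], x$n_boot))
  }
  cat(sprintf(", %d interior points\n", x$n_interior_points))
  invisible(x)
}

#' Compare nonlinearity scores across groups
#'
#' Computes one nonlinearity score per complete replicate profile in each
#' group (replicate r's own values at every night time point), then runs a
#' one-way ANOVA over these per-replicate scores followed by Tukey's HSD,
#' summarized as a compact letter display at `alpha`: groups sharing a
#' letter do not differ significantly.
#'
#' @param data A tidy starch tibble holding two or more series.
#' @param group Column that labels the groups (default `genotype`).
#' @param alpha Significance level for the letter display.
#' @param include_endpoints Passed to the per-profile score.
#' @return A list of class `nonlinearity_comparison`: per-group tibble
#'   (`group`, `mean_score`, `n`, `letters`), the `aov` fit, Tukey HSD
#'   table.
#' @export
compare_nonlinearity <- function(data, group = "genotype", alpha = 0.05,
                                 include_endpoints = TRUE) {
  groups <- split_series(dplyr::select(data, dplyr::all_of(
    intersect(names(data), diel_schema))))
  if (length(groups) < 2) {
    rlang::abort("need at least two groups to compare",
                 class = "dielstarch_insufficient_data")
  }
  per_rep <- purrr::map_dfr(groups, function(g) {
    lab <- as.character(g[[group]][1])
    reps <- unique(g$replicate)
    scores <- purrr::map_dbl(reps, function(r) {
      prof <- dplyr::filter(g, .data$replicate == r)
      res <- tryCatch(
        nonlinearity(prof, n_boot = 0,
                     include_endpoints = include_endpoints),
        error = function(e) NULL)
      if (is.null(res)) NA_real_ else res$score
    })
    tibble::tibble(group = lab, replicate = reps, score = scores)
  })
  per_rep <- dplyr::filter(per_rep, !is.na(.data$score))
  per_rep$group <- factor(per_rep$group)
  fit <- stats::aov(score ~ group, data = per_rep)
  letters <- tukey_letters(fit, alpha = alpha)
  summary_tbl <- per_rep |>
    dplyr::group_by(group = .data$group) |>
    dplyr::summarise(mean_score = mean(.data$score), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(letters = unname(letters[as.character(.data$group)]))
  structure(
    list(summary = summary_tbl, per_replicate = per_rep, fit = fit,
         tukey = stats::TukeyHSD(fit), alpha = alpha),
    class = "nonlinearity_comparison"
  )
}

#' @export
print.nonlinearity_comparison <- function(x, ...) {
  cat("<nonlinearity_comparison>\n")
  print(x$summary)
  invisible(x)
}
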