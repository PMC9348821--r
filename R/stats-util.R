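#' Nonparametric bootstrap percentile confidence interval
#'
#' Resamples values with replacement (within groups, when `group` is
#' given), recomputes `statistic` on each draw, and returns the 2.5/97.5
#' percentile bounds.
#'
#' @param values Numeric vector of observations.
#' @param statistic Function of a numeric vector (default `mean`). When
#'   grouped, it receives the whole resampled vector.
#' @param n_boot Number of bootstrap draws.
#' @param seed Optional integer seed.
#' @param group Optional grouping vector (same length as `values`);
#'   resampling is stratified within groups, preserving the design.
#' @return A list of class `bootstrap_ci`: `estimate`, `lo`, `hi`,
#'   `n_boot`, `seed`, `method = "percentile"`, `degenerate` (any stratum
#'   of size 1).
#' @examples
#' bootstrap_ci(rnorm(20), mean, n_boot = 200, seed = 1)
#' @export
bootstrap_ci <- function(values, statistic = mean, n_boot = 1000,
                         seed = NULL, group = NULL) {
  stopifnot(length(values) >= 1)
  if (is.null(group)) group <- rep(1L, length(values))
  idx_by_group <- split(seq_along(values), group)
  degenerate <- any(lengths(idx_by_group) == 1L)
  if (degenerate) {
    rlang::warn("bootstrap_ci: a stratum has a single observation; CI is degenerate there")
  }
  draw_stats <- function() {
    vapply(seq_len(n_boot), function(i) {
      idx <- unlist(lapply(idx_by_group, function(ix)
        ix[sample.int(length(ix), replace = TRUE)]), use.names = FALSE)
      statistic(values[idx])
    }, numeric(1))
  }
  stats_b <- if (is.null(seed)) draw_stats()
             else withr::with_seed(seed, draw_stats())
  qs <- stats::quantile(stats_b, c(0.025, 0.975), names = FALSE)
  structure(
    list(estimate = statistic(values), lo = qs[1], hi = qs[2],
         n_boot = n_boot, seed = seed, method = "percentile",
         degenerate = degenerate, boot_stats = stats_b),
    class = "bootstrap_ci"
  )
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("<bootstrap_ci> %.4g (95%% percentile CI %.4g to %.4g, %d draws)\n",
              x$estimate, x$lo, x$hi, x$n_boot))
  invisible(x)
}

#' Per-time-point and interval ANOVA for diel series
#'
#' One-way ANOVA comparing groups (e.g. genotypes) at each sampled ZT, the
#' standard per-time-point significance test annotated on diel plots.
#' Groups with zero within- and between-group variance short-circuit to
#' `F = 0, p = 1`.
#'
#' @param data Tidy tibble with several series differing in `group`.
#' @param group Grouping column name (default `"genotype"`).
#' @return A tibble with one row per ZT: `zt`, `f`, `p`, `stars`, `n`.
#' @export
anova_timepoint <- function(data, group = "genotype") {
  data |>
    dplyr::group_by(zt = .data$zt) |>
    dplyr::group_modify(function(d, key) {
      g <- factor(d[[group]])
      if (nlevels(g) < 2 || any(table(g) < 2)) {
        return(tibble::tibble(f = NA_real_, p = NA_real_,
                              stars = "NA", n = nrow(d)))
      }
      if (stats::var(d$value) == 0) {
        return(tibble::tibble(f = 0, p = 1, stars = "", n = nrow(d)))
      }
      fit <- stats::aov(d$value ~ g)
      tab <- summary(fit)[[1]]
      tibble::tibble(f = tab[["F value"]][1], p = tab[["Pr(>F)"]][1],
                     stars = sig_stars(tab[["Pr(>F)"]][1]), n = nrow(d))
    }) |>
    dplyr::ungroup()
}

#' Compact letter display from a one-way fit
#'
#' Runs Tukey's HSD (Tukey-Kramer on unbalanced groups) via
#' single-step-adjusted pairwise contrasts and condenses the result into
#' letters: groups sharing any letter are not significantly different at
#' `alpha`.
#'
#' @param fit An `aov` fit with a single factor term named `group`.
#' @param alpha Significance level.
#' @return Named character vector of letters, one per group level.
#' @export
tukey_letters <- function(fit, alpha = 0.05) {
  term <- attr(stats::terms(fit), "term.labels")[1]
  glht_args <- stats::setNames(list("Tukey"), term)
  comp <- multcomp::glht(fit, linfct = do.call(multcomp::mcp, glht_args))
  cld <- multcomp::cld(comp, level = alpha)
  cld$mcletters$Letters
}

# summary.lm warns on exact (noise-free) data; the zero-variance case is
# legitimate here, so muffle just that warning.
quiet_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

#' Significance stars
#'
#' Standard significance coding: `***` below 0.001, `**` below 0.01,
#' `*` below 0.05, empty otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star codes.
#' @export
sig_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "NA",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Two-way type II ANOVA over a time interval
#'
#' Fits `value ~ group * zt` with ZT as a categorical factor over the
#' interval and reports type II sums of squares — the convention for
#' testing genotype and genotype-by-time effects over a window of a diel
#' course.
#'
#' @param data Tidy tibble with several series differing in `group`.
#' @param group Grouping column name.
#' @param window Optional ZT window `c(start, end)`, closed.
#' @return A list with the `lm` fit and the car::Anova type II table.
#' @export
anova_interval <- function(data, group = "genotype", window = NULL) {
  if (!is.null(window)) {
    data <- dplyr::filter(data, .data$zt >= window[1] - 1e-9,
                          .data$zt <= window[2] + 1e-9)
  }
  d <- tibble::tibble(value = data$value,
                      group = factor(data[[group]]),
                      zt = factor(data$zt))
  fit <- stats::lm(value ~ group * zt, data = d)
  list(fit = fit, anova = car::Anova(fit, type = 2))
}
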