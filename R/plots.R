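#' Plot a diel time course
#'
#' Mean ± bootstrapped 95% CI per time point for each series in the table,
#' with night shading, the standard presentation of diel metabolite and
#' transcript courses.
#'
#' @param data A tidy diel tibble (one or more series of one variable).
#' @param colour Column mapped to colour (default `genotype`).
#' @param n_boot Bootstrap draws for the per-point CI.
#' @param seed Seed for the bootstrap.
#' @return A ggplot object.
#' @export
plot_diel <- function(data, colour = "genotype", n_boot = 200, seed = 1) {
  regime <- regime_from_data(data)
  summ <- data |>
    dplyr::group_by(.data[[colour]], zt = .data$zt) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2) {
        return(tibble::tibble(mean = mean(d$value), lo = NA_real_,
                              hi = NA_real_))
      }
      ci <- bootstrap_ci(d$value, mean, n_boot = n_boot, seed = seed)
      tibble::tibble(mean = ci$estimate, lo = ci$lo, hi = ci$hi)
    }) |>
    dplyr::ungroup()
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$zt, y = .data$mean,
                                     colour = .data[[colour]])) +
    ggplot2::annotate("rect", xmin = effective_dusk_zt(regime),
                      xmax = regime$cycle_length_h, ymin = -Inf, ymax = Inf,
                      fill = "grey85", alpha = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.3, na.rm = TRUE) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "ZT (h after dawn)", y = data$variable[1]) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the fit behind a slope estimate
#'
#' @param object A `slope_fit`.
#' @param ... Unused.
#' @return A ggplot of the replicate points in the fit window and the
#'   fitted line.
#' @exportS3Method ggplot2::autoplot
autoplot.slope_fit <- function(object, ...) {
  d <- object$fit$model
  ggplot2::ggplot(d, ggplot2::aes(x = .data$zt, y = .data$.y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope, colour = "steelblue") +
    ggplot2::labs(
      x = "ZT (h after dawn)",
      y = if (object$normalized) "fraction of dusk value" else "value",
      title = sprintf("slope %.3g (95%% CI %.3g to %.3g)", object$slope,
                      object$ci95[1], object$ci95[2])
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-time-point deviation from linear mobilization
#'
#' @param object A `nonlinearity_result`.
#' @param ... Unused.
#' @return A ggplot of normalized residues against ZT with the score as a
#'   reference line.
#' @exportS3Method ggplot2::autoplot
autoplot.nonlinearity_result <- function(object, ...) {
  ggplot2::ggplot(object$per_point_residues,
                  ggplot2::aes(x = .data$zt, y = .data$residue)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_hline(yintercept = object$score, linetype = 2,
                        colour = "firebrick") +
    ggplot2::geom_col(width = 0.6, fill = "steelblue") +
    ggplot2::labs(x = "ZT (h after dawn)",
                  y = "(observed - predicted) / predicted",
                  title = sprintf("nonlinearity score %.3f", object$score)) +
    ggplot2::theme_minimal()
}

#' Plot the bootstrap peak distribution
#'
#' @param object A `rhythm_feature` from [peak_time()].
#' @param ... Unused.
#' @return A ggplot histogram of per-draw peak times by method.
#' @exportS3Method ggplot2::autoplot
autoplot.rhythm_feature <- function(object, ...) {
  if (is.null(object$method_peaks)) {
    rlang::abort("no bootstrap peak detail to plot; run peak_time() first")
  }
  d <- dplyr::filter(object$method_peaks, !is.na(.data$peak_uzt))
  d$peak <- wrap_zt(d$peak_uzt, object$cycle_length_h)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$peak,
                                       fill = .data$method)) +
    ggplot2::geom_histogram(binwidth = 0.5, position = "identity",
                            alpha = 0.6) +
    ggplot2::labs(x = "peak ZT (h after dawn)", y = "bootstrap draws") +
    ggplot2::theme_minimal()
  if (isTRUE(object$scorable)) {
    p <- p + ggplot2::geom_vline(xintercept = object$peak_zt,
                                 linetype = 2)
  }
  p
}

#' Heatmap of scaled alignment scores
#'
#' @param scores A tibble as returned by [scale_alignment_scores()], with
#'   columns `transcript`, `anchor`, and the scaled scores.
#' @param score Which scaled score to show, `"dist_scaled"` or
#'   `"norm_scaled"`.
#' @return A ggplot tile map (0 = best alignment, 1 = worst).
#' @export
plot_alignment <- function(scores, score = c("dist_scaled", "norm_scaled")) {
  score <- match.arg(score)
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$anchor,
                                       y = .data$transcript,
                                       fill = .data[[score]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(fill = score) +
    ggplot2::theme_minimal()
}
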