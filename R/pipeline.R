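#' Run a simulate-and-analyze pipeline from a scenario description
#'
#' Reads a scenario (a YAML file or an equivalent nested list) describing
#' genotypes x light regimes x variables, simulates every series, runs the
#' enabled analysis stages, and writes per-stage TSV tables plus a
#' machine-readable JSON summary into `out_dir`. Given the same scenario
#' and seed the whole bundle is byte-identical across runs; the seed is
#' recorded in the summary and each series draws from a seed derived
#' deterministically from it.
#'
#' Scenario structure (YAML keys): `name`; `sample_every_h`; `genotypes:`
#' a list of `{name, starch: <starch_model fields>, transcripts: [<gene +
#' transcript_model fields>]}`; `regimes:` a list of `light_regime`
#' fields; `stages:` logical toggles `rates`, `stex`, `linearity`,
#' `peaks`; `cap_darkness_h` (default 8.5); `n_boot`; `alpha`.
#'
#' @param scenario Path to a YAML scenario file, or a list.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer master seed.
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(scenario, out_dir, seed = 1) {
  if (is.character(scenario)) scenario <- yaml::read_yaml(scenario)
  if (is.null(scenario$genotypes) || length(scenario$genotypes) == 0 ||
      is.null(scenario$regimes) || length(scenario$regimes) == 0) {
    rlang::abort("scenario must define at least one genotype and one regime",
                 class = "dielstarch_scenario_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- utils::modifyList(
    list(rates = TRUE, stex = TRUE, linearity = TRUE, peaks = TRUE),
    scenario$stages %||% list())
  step_h <- scenario$sample_every_h %||% 2
  cap <- scenario$cap_darkness_h %||% 8.5
  n_boot <- scenario$n_boot %||% 200

  regimes <- lapply(scenario$regimes, function(r) do.call(light_regime, r))

  sim <- list(); k <- 0L
  for (g in scenario$genotypes) {
    for (ri in seq_along(regimes)) {
      r <- regimes[[ri]]
      if (!is.null(g$starch)) {
        k <- k + 1L
        m <- do.call(starch_model, g$starch)
        m <- apply_perturbation(m, r)
        sim[[length(sim) + 1L]] <- simulate_starch(
          m, r, sample_every_h = step_h, genotype = g$name,
          experiment_id = scenario$name %||% "scenario",
          seed = seed + 1000L * k)
      }
      for (tr in g$transcripts %||% list()) {
        k <- k + 1L
        gene <- tr$gene; tr$gene <- NULL
        m <- do.call(transcript_model, tr)
        sim[[length(sim) + 1L]] <- simulate_transcript(
          m, r, sample_every_h = step_h, gene = gene, genotype = g$name,
          experiment_id = scenario$name %||% "scenario",
          seed = seed + 1000L * k)
      }
    }
  }
  data <- dplyr::bind_rows(sim)
  write_diel(data, file.path(out_dir, "simulated.tsv"))

  starch <- dplyr::filter(data, .data$variable == "starch")
  transcripts <- dplyr::filter(data,
                               startsWith(.data$variable, "transcript:"))
  summary <- list(scenario = scenario$name %||% "scenario", seed = seed,
                  sample_every_h = step_h, n_series = length(sim))

  if (isTRUE(stages$rates) && nrow(starch) > 0) {
    rates <- purrr::imap_dfr(split_series(starch), function(s, nm) {
      dplyr::bind_cols(
        tibble::tibble(series = nm, rate = c("accumulation", "mobilization")),
        dplyr::bind_rows(tidy(accumulation_rate(s)),
                         tidy(mobilization_rate(s, cap_darkness_h = cap))))
    })
    readr::write_tsv(rates, file.path(out_dir, "rates.tsv"))
    summary$rates <- nrow(rates)
  }
  if (isTRUE(stages$stex) && nrow(starch) > 0) {
    ex <- purrr::imap_dfr(split_series(starch), function(s, nm) {
      dplyr::bind_cols(tibble::tibble(series = nm),
                       dplyr::bind_rows(tidy(stex(s)),
                                        tidy(stex_app(s, cap))))
    })
    readr::write_tsv(ex, file.path(out_dir, "exhaustion.tsv"))
    summary$exhaustion <- nrow(ex)
  }
  if (isTRUE(stages$linearity) && nrow(starch) > 0) {
    lin <- purrr::imap_dfr(split_series(starch), function(s, nm) {
      res <- nonlinearity(s, n_boot = n_boot, seed = seed)
      dplyr::bind_cols(tibble::tibble(series = nm), glance(res))
    })
    readr::write_tsv(lin, file.path(out_dir, "nonlinearity.tsv"))
    summary$nonlinearity <- nrow(lin)
  }
  if (isTRUE(stages$peaks) && nrow(transcripts) > 0) {
    pk <- purrr::imap_dfr(split_series(transcripts), function(s, nm) {
      pt <- peak_time(s, seed = seed)
      am <- amplitude(s)
      dplyr::bind_cols(tibble::tibble(series = nm),
                       tidy(pt)[, c("peak_zt", "peak_lo", "peak_hi",
                                    "scorable")],
                       tidy(am)[, c("amplitude", "amp_lo", "amp_hi")])
    })
    readr::write_tsv(pk, file.path(out_dir, "peaks.tsv"))
    summary$peaks <- nrow(pk)
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}

#' Recompute the headline starch and rhythm statistics from deposited data
#'
#' Given the study's replicate metabolite (and optionally transcript)
#' tables converted to the package's tidy TSV schema, recomputes, per
#' series: accumulation and mobilization rates, single-extrapolation StEx
#' with its SE, nested-window apparent StEx with its CI, the nonlinearity
#' score, and (for transcripts) bootstrap peak time and amplitude. This is
#' the reproduction path for the published supplementary tables; it makes
#' no assumptions beyond the schema.
#'
#' @param starch_path Tidy TSV of starch series (see [read_diel()]).
#' @param transcript_path Optional tidy TSV of transcript series.
#' @param cap_darkness_h Darkness cap for the nested StEx fits.
#' @param seed Seed for bootstrap stages.
#' @return A list of tibbles: `rates`, `exhaustion`, `nonlinearity`, and
#'   (if transcripts given) `peaks`.
#' @export
reproduce_supplementary <- function(starch_path, transcript_path = NULL,
                                    cap_darkness_h = 8.5, seed = 1) {
  starch <- read_diel(starch_path)
  out <- list()
  series <- split_series(dplyr::filter(starch, .data$variable == "starch"))
  out$rates <- purrr::imap_dfr(series, function(s, nm) {
    dplyr::bind_cols(
      tibble::tibble(series = nm, rate = c("accumulation", "mobilization")),
      dplyr::bind_rows(tidy(accumulation_rate(s)),
                       tidy(mobilization_rate(s))))
  })
  out$exhaustion <- purrr::imap_dfr(series, function(s, nm) {
    dplyr::bind_cols(tibble::tibble(series = nm),
                     dplyr::bind_rows(tidy(stex(s)),
                                      tidy(stex_app(s, cap_darkness_h))))
  })
  out$nonlinearity <- purrr::imap_dfr(series, function(s, nm) {
    dplyr::bind_cols(tibble::tibble(series = nm),
                     glance(nonlinearity(s, n_boot = 1000, seed = seed)))
  })
  if (!is.null(transcript_path)) {
    tr <- read_diel(transcript_path)
    out$peaks <- purrr::imap_dfr(
      split_series(dplyr::filter(tr, startsWith(.data$variable,
                                                "transcript:"))),
      function(s, nm) {
        dplyr::bind_cols(tibble::tibble(series = nm),
                         tidy(peak_time(s, seed = seed)))
      })
  }
  out
}
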