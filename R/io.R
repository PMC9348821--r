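#' @importFrom rlang .data
NULL

# Canonical column order of the tidy diel time-series schema.
diel_schema <- c("experiment_id", "genotype", "cycle_length_h", "photoperiod_h",
                 "irradiance", "perturbation", "zt", "variable", "unit",
                 "replicate", "value")

diel_required <- c("genotype", "cycle_length_h", "photoperiod_h",
                   "zt", "variable", "unit", "replicate", "value")

metabolite_vars <- c("starch", "glucose", "fructose", "sucrose")

#' Read a tidy diel time-series table
#'
#' Reads a tab-delimited (or comma-delimited) table of replicate diel
#' measurements into a tibble, validating the schema. One row is one
#' replicate measurement of one variable at one ZT. Rows with `value` of
#' `NA` are dropped with a message reporting how many.
#'
#' Required columns: `genotype`, `cycle_length_h`, `photoperiod_h`, `zt`,
#' `variable`, `unit`, `replicate`, `value`; optional: `experiment_id`,
#' `irradiance`, `perturbation`. The missing-value marker is literal `"NA"`.
#'
#' @param path Path to a TSV/CSV file.
#' @param delim Field delimiter; `"\t"` (default) or `","`.
#' @return A tibble with one validated row per retained measurement.
#' @seealso [write_diel()]
#' @export
read_diel <- function(path, delim = "\t") {
  data <- readr::read_delim(path, delim = delim, na = "NA",
                            show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(diel_required, names(data))
  if (length(missing_cols) > 0) {
    rlang::abort(
      sprintf("input is missing required column(s): %s",
              paste(missing_cols, collapse = ", ")),
      class = "dielstarch_schema_error"
    )
  }
  n_na <- sum(is.na(data$value))
  if (n_na > 0) {
    rlang::inform(sprintf("read_diel: dropped %d row(s) with missing values", n_na))
    data <- dplyr::filter(data, !is.na(.data$value))
  }
  validate_diel(data)
  data
}

#' Write a tidy diel time-series table
#'
#' Writes the canonical tab-delimited representation (header line, `"NA"`
#' missing marker, UTF-8). Values round-trip through [read_diel()] exactly
#' at full double precision.
#'
#' @param data A tidy diel tibble (see [read_diel()] for the schema).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_diel <- function(data, path) {
  validate_diel(data)
  cols <- intersect(diel_schema, names(data))
  data <- dplyr::select(data, dplyr::all_of(cols), dplyr::everything())
  readr::write_tsv(data, path, na = "NA")
  invisible(path)
}

# Validate invariants of a tidy diel table; aborts on violation.
validate_diel <- function(data) {
  bad <- which(data$variable %in% metabolite_vars & !is.na(data$value) &
                 data$value < 0)
  if (length(bad) > 0) {
    rlang::abort(
      sprintf("negative metabolite value(s) at row(s): %s",
              paste(utils::head(bad, 5), collapse = ", ")),
      class = "dielstarch_validation_error"
    )
  }
  out_of_cycle <- which(data$zt < 0 | data$zt > data$cycle_length_h)
  if (length(out_of_cycle) > 0) {
    rlang::abort(
      sprintf("zt outside [0, cycle_length_h] at row(s): %s",
              paste(utils::head(out_of_cycle, 5), collapse = ", ")),
      class = "dielstarch_validation_error"
    )
  }
  invisible(data)
}

# Assert a tibble holds exactly one series (one genotype x regime x variable).
one_series <- function(data) {
  keys <- c("genotype", "variable", "cycle_length_h", "photoperiod_h",
            "perturbation", "experiment_id")
  keys <- intersect(keys, names(data))
  n <- nrow(dplyr::distinct(data, dplyr::across(dplyr::all_of(keys))))
  if (n != 1L) {
    rlang::abort(
      paste0("expected a single series (one genotype × regime × variable), found ",
             n, "; group or filter the table first"),
      class = "dielstarch_series_error"
    )
  }
  invisible(data)
}

#' Split a tidy table into its component series
#'
#' @param data A tidy diel tibble holding one or more series.
#' @return A named list of single-series tibbles, keyed by
#'   `genotype/variable/T<cycle>/P<photoperiod>` (plus experiment and
#'   perturbation when present).
#' @export
split_series <- function(data) {
  keys <- intersect(c("experiment_id", "genotype", "variable", "cycle_length_h",
                      "photoperiod_h", "irradiance", "perturbation"),
                    names(data))
  grouped <- dplyr::group_by(data, dplyr::across(dplyr::all_of(keys)))
  parts <- dplyr::group_split(grouped)
  labels <- dplyr::group_keys(grouped)
  nm <- apply(labels, 1, function(r) paste(r[nzchar(r) & !is.na(r)], collapse = "/"))
  stats::setNames(lapply(parts, tibble::as_tibble), nm)
}

#' Aggregate a series into a dawn- or dusk-aligned mean profile
#'
#' Computes the per-time-point mean and standard error of one series and
#' re-expresses the time axis relative to an anchor. Dawn anchoring leaves
#' ZT unchanged. Dusk anchoring sets offset 0 at dusk
#' (`zt - photoperiod_h` for night points) and rotates pre-dusk points into
#' the same cycle (`zt + cycle_length_h - photoperiod_h`), so that offsets
#' run over one full cycle starting at lights-off.
#'
#' @param data A single-series tidy tibble.
#' @param anchor `"dawn"` or `"dusk"`.
#' @return A tibble with columns `offset` (hours after the anchor,
#'   increasing), `mean`, `sem` (`NA` where only one replicate was
#'   measured), and `n` (replicates).
#' @examples
#' reg <- light_regime(24, 12)
#' s <- simulate_starch(starch_model(noise_frac = 0), reg, seed = 1)
#' mean_profile(s, anchor = "dusk")
#' @export
mean_profile <- function(data, anchor = c("dawn", "dusk")) {
  anchor <- match.arg(anchor)
  one_series(data)
  regime <- regime_from_data(data)
  p <- regime$photoperiod_h
  tt <- regime$cycle_length_h
  # Offset is assigned per measurement, then replicates pooled per offset, so
  # a dawn sample recorded at both ZT0 and ZT cycle_length pools cleanly.
  data <- dplyr::mutate(
    data,
    offset = if (anchor == "dawn") .data$zt
             else ifelse(.data$zt >= p, .data$zt - p, .data$zt + (tt - p))
  )
  data |>
    dplyr::group_by(offset = .data$offset) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sem = if (dplyr::n() > 1) stats::sd(.data$value) / sqrt(dplyr::n()) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$offset)
}
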