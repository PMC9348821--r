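#' Parameterize a synthetic diel starch trajectory
#'
#' The noiseless mean trajectory is piecewise: linear accumulation from dawn
#' to dusk at rate `accum_rate` (so dusk starch is `accum_rate * photoperiod`),
#' then decay to zero at ZT `exhaustion_zt` following
#' `S_dusk * (1 - (t - P)/(E - P))^curvature`, and zero afterwards.
#' `curvature = 1` gives linear mobilization; `curvature > 1` mobilizes fast
#' early in the night, `curvature < 1` slow early. Replicate noise is
#' additive Gaussian with standard deviation `noise_frac * S_dusk`
#' (anchored to dusk starch so that scatter does not vanish near dawn),
#' and noised values are clipped at zero.
#'
#' @param accum_rate Daytime accumulation rate, µmol Glc-equivalents
#'   g⁻¹ FW h⁻¹.
#' @param exhaustion_zt ZT (hours after dawn) at which the mean trajectory
#'   reaches zero starch; must exceed the photoperiod.
#' @param curvature Night-shape exponent γ > 0; 1 = linear.
#' @param noise_frac Replicate SD as a fraction of dusk starch.
#' @param n_reps Biological replicates per time point.
#' @return An object of class `starch_model`.
#' @seealso [simulate_starch()], [apply_perturbation()]
#' @export
starch_model <- function(accum_rate = 1, exhaustion_zt = 24, curvature = 1,
                         noise_frac = 0.05, n_reps = 4) {
  stopifnot(accum_rate > 0, curvature > 0, noise_frac >= 0, n_reps >= 1)
  structure(
    list(accum_rate = accum_rate, exhaustion_zt = exhaustion_zt,
         curvature = curvature, noise_frac = noise_frac,
         n_reps = as.integer(n_reps)),
    class = "starch_model"
  )
}

# Noiseless mean starch at ZT t under model m in regime r.
starch_mean_fn <- function(m, r) {
  p <- effective_dusk_zt(r)
  e <- m$exhaustion_zt
  s_dusk <- m$accum_rate * p
  function(t) {
    ifelse(t <= p, m$accum_rate * t,
           ifelse(t < e, s_dusk * (1 - (t - p) / (e - p))^m$curvature, 0))
  }
}

#' Simulate a replicate diel starch series
#'
#' Samples the [starch_model()] mean trajectory on a regular ZT grid covering
#' the full cycle and adds independent Gaussian replicate noise.
#'
#' @param model A [starch_model()].
#' @param regime A [light_regime()]; an early-dusk perturbation moves the
#'   accumulation/mobilization breakpoint to `early_dusk_zt`.
#' @param sample_every_h Sampling interval in hours (grid `0, Δ, …,
#'   cycle_length_h`); the grid must land exactly on dusk, which downstream
#'   rate fits require.
#' @param genotype,experiment_id Labels carried into the output table.
#' @param seed Optional integer seed; fixed seed gives bit-identical output.
#' @return A tidy diel tibble (see [read_diel()]) with `variable = "starch"`,
#'   unit µmol Glc-equivalents g⁻¹ FW.
#' @examples
#' s <- simulate_starch(starch_model(noise_frac = 0), light_regime(24, 12))
#' mean_profile(s)
#' @export
simulate_starch <- function(model, regime, sample_every_h = 2,
                            genotype = "synthetic", experiment_id = "sim",
                            seed = NULL) {
  stopifnot(model$exhaustion_zt > effective_dusk_zt(regime))
  grid <- seq(0, regime$cycle_length_h, by = sample_every_h)
  dusk <- effective_dusk_zt(regime)
  if (!any(abs(grid - dusk) < 1e-9)) {
    rlang::abort(
      sprintf("sampling grid (every %g h) does not include dusk at ZT%g",
              sample_every_h, dusk),
      class = "dielstarch_grid_error"
    )
  }
  mean_fn <- starch_mean_fn(model, regime)
  s_dusk <- model$accum_rate * dusk
  sd_noise <- model$noise_frac * s_dusk
  draw <- function() {
    tidyr::expand_grid(zt = grid, replicate = seq_len(model$n_reps)) |>
      dplyr::mutate(
        value = pmax(0, mean_fn(.data$zt) +
                       stats::rnorm(dplyr::n(), 0, sd_noise))
      )
  }
  pts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  dplyr::bind_cols(
    tibble::tibble(experiment_id = experiment_id, genotype = genotype),
    regime_cols(regime)[rep(1, nrow(pts)), ],
    pts
  ) |>
    dplyr::mutate(variable = "starch", unit = "umol_gFW",
                  .before = "replicate")
}

#' Parameterize a synthetic oscillating transcript
#'
#' The noiseless mean on the log2 scale is
#' `baseline + damping * amplitude * g(d)`, where `d` is the circular
#' distance (in hours, modulo the cycle length) between ZT and the peak
#' time, and `g` is a raised-cosine bump: `g(d) = (1 + cos(pi d / w))/2`
#' for `d < w`, zero beyond. The bump reaches 1 at the peak and 0 at
#' distance `peak_width`, giving the sharp peaks typical of clock
#' transcripts with a directly controllable width. Noise is additive
#' Gaussian on the log2 scale.
#'
#' @param baseline Trough expression, log2(copies × 2.5e7 g⁻¹ FW).
#' @param amplitude Peak height above baseline, log2 units.
#' @param peak_zt ZT of peak expression, hours.
#' @param peak_width Half-width of the bump, hours (expression returns to
#'   baseline `peak_width` hours either side of the peak).
#' @param damping Multiplier in (0, 1] on the amplitude (models loss of
#'   amplitude in clock mutants).
#' @param noise_sd Replicate SD, log2 units.
#' @param n_reps Replicates per time point.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(baseline = 10, amplitude = 4, peak_zt = 4,
                             peak_width = 6, damping = 1, noise_sd = 0.3,
                             n_reps = 3) {
  stopifnot(amplitude >= 0, peak_width > 0, damping > 0, damping <= 1,
            noise_sd >= 0, n_reps >= 1)
  structure(
    list(baseline = baseline, amplitude = amplitude, peak_zt = peak_zt,
         peak_width = peak_width, damping = damping, noise_sd = noise_sd,
         n_reps = as.integer(n_reps)),
    class = "transcript_model"
  )
}

# Circular distance between times a and b on a cycle of length t_cycle.
circ_dist <- function(a, b, t_cycle) {
  d <- abs(a - b) %% t_cycle
  pmin(d, t_cycle - d)
}

# Noiseless mean transcript level at ZT t.
transcript_mean_fn <- function(m, r) {
  function(t) {
    d <- circ_dist(t, m$peak_zt, r$cycle_length_h)
    bump <- ifelse(d < m$peak_width, (1 + cos(pi * d / m$peak_width)) / 2, 0)
    m$baseline + m$damping * m$amplitude * bump
  }
}

#' Simulate a replicate diel transcript series
#'
#' @param model A [transcript_model()].
#' @param regime A [light_regime()].
#' @param sample_every_h Sampling interval in hours.
#' @param gene Gene label; the output `variable` is `"transcript:<gene>"`.
#' @param genotype,experiment_id Labels carried into the output table.
#' @param seed Optional integer seed.
#' @return A tidy diel tibble with unit `log2_copies_per_2.5e7_gFW`.
#' @export
simulate_transcript <- function(model, regime, sample_every_h = 2,
                                gene = "GENE", genotype = "synthetic",
                                experiment_id = "sim", seed = NULL) {
  grid <- seq(0, regime$cycle_length_h, by = sample_every_h)
  mean_fn <- transcript_mean_fn(model, regime)
  draw <- function() {
    tidyr::expand_grid(zt = grid, replicate = seq_len(model$n_reps)) |>
      dplyr::mutate(
        value = mean_fn(.data$zt) + stats::rnorm(dplyr::n(), 0, model$noise_sd)
      )
  }
  pts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  dplyr::bind_cols(
    tibble::tibble(experiment_id = experiment_id, genotype = genotype),
    regime_cols(regime)[rep(1, nrow(pts)), ],
    pts
  ) |>
    dplyr::mutate(variable = paste0("transcript:", gene),
                  unit = "log2_copies_per_2.5e7_gFW",
                  .before = "replicate")
}

#' Apply a harvest-day light perturbation to a starch model
#'
#' Adjusts the generator parameters the way the perturbation changes the
#' plant's carbon budget: a low-light day scales the accumulation rate by
#' the irradiance ratio (starch accumulation is roughly light-limited); an
#' early dusk truncates the light phase at `early_dusk_zt`, so dusk starch
#' falls proportionally. What the night does afterwards — whether
#' mobilization re-paces to the anticipated dawn (compensating) or keeps the
#' baseline rate (non-compensating) — is the caller's choice via
#' `night_policy`.
#'
#' @param model A baseline [starch_model()] describing the unperturbed day.
#' @param regime A [light_regime()] whose `perturbation` describes the
#'   treatment; `"none"` returns the model unchanged.
#' @param night_policy For early dusk: `"compensating"` keeps
#'   `exhaustion_zt` at its baseline value (mobilization slows to still
#'   exhaust at anticipated dawn); `"non_compensating"` keeps the baseline
#'   mobilization *rate*, so exhaustion comes earlier.
#' @return A [starch_model()] with adjusted parameters.
#' @examples
#' m <- starch_model(accum_rate = 1, exhaustion_zt = 24)
#' r <- light_regime(24, 12, 160, "early_dusk", early_dusk_zt = 8)
#' apply_perturbation(m, r)
#' @export
apply_perturbation <- function(model, regime,
                               night_policy = c("compensating",
                                                "non_compensating")) {
  night_policy <- match.arg(night_policy)
  switch(
    regime$perturbation,
    none = model,
    extended_night = model,
    low_light_day = {
      model$accum_rate <- model$accum_rate *
        regime$low_light_irradiance / regime$irradiance
      model
    },
    early_dusk = {
      if (night_policy == "non_compensating") {
        p0 <- regime$photoperiod_h
        rate <- model$accum_rate * p0 / (model$exhaustion_zt - p0)
        s_dusk_new <- model$accum_rate * regime$early_dusk_zt
        model$exhaustion_zt <- regime$early_dusk_zt + s_dusk_new / rate
      }
      # compensating: exhaustion_zt untouched; mobilization slope adapts
      model
    }
  )
}
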