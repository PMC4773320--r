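#' First-in-human single-ascending-dose trial design
#'
#' Describes the emulated trial: five dose cohorts between 45 and 720 mg (only
#' the extremes and the total of 20 subjects are fixed by the study report;
#' the intermediate levels are declared, configurable assumptions), injected
#' concentrations of 100-150 mg/mL so single-injection volumes stay at or
#' below 2 mL (the depot volume is the sum over injections), abdominal SC
#' dosing, sampling to about 1050 h, a 1 ug/mL limit of quantitation, and a
#' combined proportional + additive residual error model.
#'
#' @param cohorts Tibble with columns `dose_mg`, `conc_mg_ml`, `n_subjects`.
#' @param sampling_times Nominal post-dose sampling times, h.
#' @param loq Limit of quantitation, ug/mL.
#' @param error_prop_cv Proportional residual error CV (fraction).
#' @param error_add_sd Additive residual error SD, ug/mL.
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(cohorts = NULL,
                         sampling_times = c(0.5, 1, 2, 4, 8, 12, 24, 48, 72,
                                            120, 168, 240, 336, 504, 672,
                                            840, 1050),
                         loq = 1,
                         error_prop_cv = 0.15,
                         error_add_sd = 0.5) {
  cohorts <- cohorts %||% tibble(
    dose_mg = c(45, 90, 180, 360, 720),
    conc_mg_ml = c(100, 100, 150, 150, 150),
    n_subjects = c(4L, 4L, 4L, 4L, 4L)
  )
  stopifnot(all(c("dose_mg", "conc_mg_ml", "n_subjects") %in% names(cohorts)))
  if (sum(cohorts$n_subjects) < 1) {
    abort("trial design must enrol at least one subject",
          class = "lymphpbpk_config_error")
  }
  structure(
    list(cohorts = cohorts, sampling_times = sampling_times, loq = loq,
         error_prop_cv = error_prop_cv, error_add_sd = error_add_sd),
    class = "trial_design"
  )
}

#' Generate a synthetic observed dataset
#'
#' Emulates the trial: samples accepted virtual individuals (weight and GFR
#' filters on) with per-subject Vfrac draws, simulates each subject at their
#' cohort's dose and injected concentration, applies combined proportional and
#' additive residual error, and censors below the limit of quantitation with a
#' below-limit flag. The generating parameters are returned as a truth table
#' for recovery testing.
#'
#' @param design A [trial_design()].
#' @param spec A [population_spec()].
#' @param drug A [drug_params()].
#' @param seed Integer seed; the whole dataset is reproducible bitwise.
#' @return An object of class `synthetic_trial`: `observations` (one row per
#'   subject and nominal time: `subject_id`, `cohort`, `dose_mg`,
#'   `conc_mg_ml`, `injection_volume_ml`, `time`, `conc`, `blq`), `truth`
#'   (per-subject generating parameters), the design and the seed.
#' @export
generate_trial <- function(design = trial_design(), spec = population_spec(),
                           drug = drug_params(), seed) {
  stopifnot(inherits(design, "trial_design"))
  if (missing(seed)) abort("a seed is required for trial generation")
  n_total <- sum(design$cohorts$n_subjects)
  pop <- generate_population(n_total, spec, drug, seed = seed)

  assignment <- rep(seq_len(nrow(design$cohorts)), design$cohorts$n_subjects)
  times <- design$sampling_times
  obs <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    co <- design$cohorts[assignment[i], ]
    ind <- pop[i, , drop = FALSE]
    dose <- suppressWarnings(
      dose_event(co$dose_mg, co$conc_mg_ml, vfrac = ind$vfrac)
    )
    sim <- simulate_pbpk(build_pbpk_model(ind, drug, dose), times)
    true_conc <- sim$profile$conc
    noisy <- true_conc * (1 + stats::rnorm(length(times), 0,
                                           design$error_prop_cv)) +
      stats::rnorm(length(times), 0, design$error_add_sd)
    noisy <- pmax(noisy, 0)
    obs[[i]] <- tibble(
      subject_id = i,
      cohort = assignment[i],
      dose_mg = co$dose_mg,
      conc_mg_ml = co$conc_mg_ml,
      injection_volume_ml = dose$injection_volume_ml,
      time = times,
      conc = noisy,
      blq = noisy < design$loq
    )
  }

  truth <- as_tibble(pop)[, c("id", "vfrac", "weight_kg", "height_cm",
                              "gfr_ml_min", "hematocrit")]
  names(truth)[1] <- "subject_id"
  truth$cohort <- assignment
  truth$dose_mg <- design$cohorts$dose_mg[assignment]

  structure(
    list(observations = bind_rows(obs), truth = truth,
         design = design, seed = seed),
    class = "synthetic_trial"
  )
}

#' Observed per-cohort median concentration series
#'
#' Medians of the measured concentrations (quantifiable and below-limit alike,
#' as nominal-time medians) across subjects within each cohort.
#'
#' @param observations An observations tibble as produced by
#'   [generate_trial()] (or a `synthetic_trial` object).
#' @return A tibble with `cohort`, `time`, `conc` (median).
#' @export
cohort_medians <- function(observations) {
  if (inherits(observations, "synthetic_trial")) {
    observations <- observations$observations
  }
  observations |>
    group_by(.data$cohort, .data$time) |>
    summarise(conc = stats::median(.data$conc), .groups = "drop")
}
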