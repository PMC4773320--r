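#' Default one-at-a-time mean-perturbation scenarios
#'
#' Each uncertain mean parameter is perturbed by plus/minus 10 percent, except
#' the vascular reflection scaling factor, whose upward perturbation is capped
#' at 1 percent so no single organ's effective reflection coefficient can
#' exceed 1.
#'
#' @return A tibble with columns `scenario`, `parameter`, `delta`.
#' @export
default_oat_scenarios <- function() {
  pars <- c("vfrac", "sigma_sf", "sigma_i", "nrcl", "ls", "fgfr")
  out <- tidyr::expand_grid(parameter = pars, delta = c(-0.10, 0.10))
  out$delta[out$parameter == "sigma_sf" & out$delta > 0] <- 0.01
  out$scenario <- sprintf("%s%+g%%", out$parameter, 100 * out$delta)
  out[, c("scenario", "parameter", "delta")]
}

perturb_drug <- function(drug, parameter, delta) {
  switch(parameter,
    vfrac = drug,  # handled through vfrac_scale, not the distribution
    sigma_sf = { drug$sigma_sf <- drug$sigma_sf * (1 + delta); drug },
    sigma_i = { drug$sigma_i <- drug$sigma_i * (1 + delta); drug },
    nrcl = { drug$nrcl_primate <- drug$nrcl_primate * (1 + delta); drug },
    ls = { drug$ls <- drug$ls * (1 + delta); drug },
    fgfr = { drug$fgfr <- drug$fgfr * (1 + delta); drug },
    abort(paste0("unknown sensitivity parameter: ", parameter),
          class = "lymphpbpk_config_error")
  )
}

# Dense default grid so NCA on the median profile is grid-converged.
default_sim_times <- function() {
  c(seq(0, 12, by = 0.25), seq(12.5, 48, by = 0.5), seq(49, 96, by = 1),
    seq(98, 240, by = 2), seq(245, 1050, by = 5))
}

#' One-at-a-time mean-parameter sensitivity analysis
#'
#' Simulates a common population (paired design: the same individuals and the
#' same seed under every scenario) at the lowest trial dose, perturbs one mean
#' parameter at a time, and reports the percent change in AUC(0-inf), Cmax and
#' Tmax of the pointwise-median concentration profile relative to the
#' unperturbed model.
#'
#' @param spec A [population_spec()].
#' @param drug A [drug_params()].
#' @param n Number of simulated individuals per scenario (default 100).
#' @param dose_mg,conc_mg_ml Dose (default the lowest cohort, 45 mg) and
#'   injected concentration.
#' @param seed Integer seed shared by baseline and all scenarios.
#' @param scenarios Scenario tibble as from [default_oat_scenarios()].
#' @param times Simulation grid, h.
#' @param lambda_z_points Terminal points for the NCA slope.
#' @return A tibble of class `oat_sensitivity`: one row per scenario (the
#'   baseline row has zero change by construction) with `pct_change_auc`,
#'   `pct_change_cmax`, `pct_change_tmax` and a `failed` flag for scenarios
#'   whose median profile defeated the NCA.
#' @export
run_mean_oat <- function(spec = population_spec(), drug = drug_params(),
                         n = 100, dose_mg = 45, conc_mg_ml = 100, seed,
                         scenarios = default_oat_scenarios(),
                         times = default_sim_times(),
                         lambda_z_points = 5) {
  if (missing(seed)) abort("a seed is required")
  pop <- generate_population(n, spec, drug, seed = seed)

  median_nca <- function(drug_i, vfrac_scale) {
    conc <- population_profiles(pop, drug_i, dose_mg, conc_mg_ml, times,
                                vfrac_scale = vfrac_scale)
    med <- apply(conc, 1, stats::median)
    nca(tibble(time = times[times > 0], conc = med[times > 0]),
        lambda_z_points = lambda_z_points)
  }

  base <- median_nca(drug, 1)
  rows <- purrr::pmap(scenarios, function(scenario, parameter, delta) {
    res <- tryCatch({
      drug_i <- perturb_drug(drug, parameter, delta)
      vfs <- if (parameter == "vfrac") 1 + delta else 1
      sc <- median_nca(drug_i, vfs)
      tibble(
        scenario = scenario, parameter = parameter, delta = delta,
        pct_change_auc = 100 * (sc$auc_inf - base$auc_inf) / base$auc_inf,
        pct_change_cmax = 100 * (sc$cmax - base$cmax) / base$cmax,
        pct_change_tmax = 100 * (sc$tmax - base$tmax) / base$tmax,
        failed = FALSE
      )
    }, error = function(e) {
      warn(paste0("scenario ", scenario, " failed: ", conditionMessage(e)))
      tibble(scenario = scenario, parameter = parameter, delta = delta,
             pct_change_auc = NA_real_, pct_change_cmax = NA_real_,
             pct_change_tmax = NA_real_, failed = TRUE)
    })
    res
  })
  out <- bind_rows(
    tibble(scenario = "baseline", parameter = "none", delta = 0,
           pct_change_auc = 0, pct_change_cmax = 0, pct_change_tmax = 0,
           failed = FALSE),
    bind_rows(rows)
  )
  structure(out, class = c("oat_sensitivity", class(tibble())),
            baseline_nca = base, n = n, dose_mg = dose_mg, seed = seed)
}

#' Labels of the eleven distribution-perturbation scenarios
#' @return A named character vector, names `"1"` to `"11"`.
#' @export
distribution_scenario_labels <- function() {
  c(
    "1" = "final model",
    "2" = "0.5-fold Vfrac CV",
    "3" = "2-fold Vfrac CV",
    "4" = "add 10% CV on LS",
    "5" = "add 50% CV on LS",
    "6" = "add 10% CV on sigma_i",
    "7" = "add 50% CV on sigma_i",
    "8" = "no blood-mass distribution",
    "9" = "no lymph-mass distribution",
    "10" = "no skin-mass distribution",
    "11" = "add 20% CV on FGFR"
  )
}

set_compartment_cv <- function(spec, name, cv) {
  spec$compartments$cv[spec$compartments$name == name] <- cv
  validate_population_spec(spec)
  spec
}

#' Distribution-perturbation sensitivity analysis
#'
#' Simulates a population under each of eleven scenarios that perturb, add or
#' remove one parameter distribution at a time (Vfrac CV halved/doubled; a 10
#' or 50 percent CV placed on the skin lymph-flow fraction or the lymphatic
#' reflection coefficient; the blood-, lymph- or skin-mass distribution
#' removed; a 20 percent CV placed on the renal-clearance fraction of GFR) and
#' returns the pointwise median and 5th-95th percentile concentration bands.
#' All scenarios are run at the same seed (common random numbers).
#'
#' @inheritParams run_mean_oat
#' @param n Individuals per scenario (default 1000).
#' @param scenarios Subset of scenario ids 1-11 to run.
#' @param times Output grid for the bands, h.
#' @return A tibble of class `distribution_sensitivity`: `scenario`, `label`,
#'   `time`, `p5`, `p50`, `p95`.
#' @export
run_distribution_scenarios <- function(spec = population_spec(),
                                       drug = drug_params(),
                                       n = 1000, dose_mg = 45,
                                       conc_mg_ml = 100, seed,
                                       scenarios = 1:11,
                                       times = c(0.5, 1, 2, 4, 8, 12, 24, 36,
                                                 48, 72, 96, 120, 168, 240,
                                                 336, 504, 672, 840, 1050)) {
  if (missing(seed)) abort("a seed is required")
  labels <- distribution_scenario_labels()
  bad <- setdiff(as.character(scenarios), names(labels))
  if (length(bad)) {
    abort(paste0("unknown scenario id(s): ", paste(bad, collapse = ", ")),
          class = "lymphpbpk_config_error")
  }

  run_one <- function(id) {
    spec_i <- spec
    drug_i <- drug
    overrides_cv <- NULL  # c(parameter, cv) for per-individual draws
    if (id == 2) drug_i$vfrac_cv <- drug$vfrac_cv * 0.5
    if (id == 3) drug_i$vfrac_cv <- drug$vfrac_cv * 2
    if (id == 4) overrides_cv <- c("ls", 0.10)
    if (id == 5) overrides_cv <- c("ls", 0.50)
    if (id == 6) overrides_cv <- c("sigma_i", 0.10)
    if (id == 7) overrides_cv <- c("sigma_i", 0.50)
    if (id == 8) spec_i <- set_compartment_cv(spec_i, "blood", 0)
    if (id == 9) spec_i <- set_compartment_cv(spec_i, "lymph", 0)
    if (id == 10) spec_i <- set_compartment_cv(spec_i, "skin", 0)
    if (id == 11) overrides_cv <- c("fgfr", 0.20)

    pop <- generate_population(n, spec_i, drug_i, seed = seed)
    overrides_df <- NULL
    if (!is.null(overrides_cv)) {
      par <- overrides_cv[1]
      cv <- as.numeric(overrides_cv[2])
      vals <- sample_compartment_mass(drug[[par]], cv, "lognormal", n = n)
      if (par == "sigma_i") vals <- pmin(vals, 1)
      overrides_df <- tibble(v = vals)
      names(overrides_df) <- par
    }
    conc <- population_profiles(pop, drug_i, dose_mg, conc_mg_ml, times,
                                overrides_df = overrides_df)
    q <- apply(conc, 1, stats::quantile, probs = c(0.05, 0.5, 0.95),
               names = FALSE)
    tibble(scenario = id, label = labels[[as.character(id)]], time = times,
           p5 = q[1, ], p50 = q[2, ], p95 = q[3, ])
  }

  out <- bind_rows(lapply(scenarios, run_one))
  structure(out, class = c("distribution_sensitivity", class(tibble())),
            n = n, dose_mg = dose_mg, seed = seed)
}

#' Plot distribution-sensitivity concentration bands
#'
#' @param object A `distribution_sensitivity` tibble.
#' @param log_y Log10 concentration axis.
#' @param ... Unused.
#' @return A ggplot object: median line with 5th-95th percentile ribbon,
#'   faceted by scenario.
#' @export
autoplot.distribution_sensitivity <- function(object, log_y = FALSE, ...) {
  df <- as_tibble(object)
  df$label <- factor(df$label, levels = unique(df$label))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p5, ymax = .data$p95),
                         fill = "grey75") +
    ggplot2::geom_line(ggplot2::aes(y = .data$p50), linetype = 2) +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "Time (h)", y = expression(
      "Plasma concentration (" * mu * "g/mL)")) +
    ggplot2::theme_bw()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot one-at-a-time sensitivity results
#'
#' @param object An `oat_sensitivity` tibble.
#' @param ... Unused.
#' @return A ggplot object: percent change in AUC, Cmax and Tmax per
#'   perturbation.
#' @export
autoplot.oat_sensitivity <- function(object, ...) {
  df <- as_tibble(object) |>
    filter(.data$scenario != "baseline") |>
    tidyr::pivot_longer(dplyr::starts_with("pct_change_"),
                        names_to = "metric", values_to = "pct_change",
                        names_prefix = "pct_change_")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pct_change, y = .data$scenario)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~toupper(.data$metric), scales = "free_x") +
    ggplot2::labs(x = "Change from final model (%)", y = NULL) +
    ggplot2::theme_bw()
}
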