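#' Define a subcutaneous dose event
#'
#' The injection volume is dose/concentration; the lymphatic drainage
#' compartment (LDC) volume is `vfrac` times the injection volume. Doses
#' needing more than 2 mL per injection are recorded as split across several
#' injections whose volumes sum to the total (the depot is the total volume).
#'
#' @param dose_mg Dose, mg.
#' @param conc_mg_ml Concentration of the injected solution, mg/mL.
#' @param vfrac LDC volume as a fraction of the injection volume.
#' @param max_injection_ml Largest volume allowed in a single injection.
#' @return An object of class `dose_event`.
#' @export
dose_event <- function(dose_mg, conc_mg_ml, vfrac = 0.25,
                       max_injection_ml = 2) {
  stopifnot(dose_mg > 0, conc_mg_ml > 0, vfrac > 0)
  vol <- dose_mg / conc_mg_ml
  if (vol < 0.45 || vol > 4.8) {
    warn(sprintf(
      "injection volume %.3g mL is outside the 0.45-4.8 mL trial range", vol
    ))
  }
  structure(
    list(
      dose_mg = dose_mg,
      conc_mg_ml = conc_mg_ml,
      injection_volume_ml = vol,
      n_injections = ceiling(vol / max_injection_ml),
      vfrac = vfrac,
      ldc_volume_ml = vfrac * vol
    ),
    class = "dose_event"
  )
}

# State ordering of the whole-body system. Amounts are in micrograms.
state_names <- function() {
  c("venous", "arterial", "lymph_node", "skin_depot", "ldc",
    paste0("vas_", ORGANS), paste0("int_", ORGANS),
    "cleared_renal", "cleared_nonrenal")
}

#' Build the whole-body PBPK model for one individual and one dose
#'
#' Assembles the linear transfer-rate matrix of the whole-body system: venous
#' and arterial plasma, a lymph-node compartment, a skin depot holding the
#' injected volume, the LDC, and vascular plus interstitial sub-compartments
#' for 15 organs. Lung sits in series on total plasma flow; spleen, pancreas
#' and the intestines drain through the liver vascular space. Transcapillary
#' transport is convective: filtrate `L_i` crosses each organ's vascular wall
#' carrying solute at `L_i (1 - sigma_sf * sigma_v_i) C_vas`, and lymph drains
#' the interstitium to the lymph node at `L_i (1 - sigma_i) C_int`. The depot
#' drains into the LDC at `Q_dep (1 - sigma_i) C_dep` with
#' `Q_dep = L_skin V_dep / V_int,skin` (or the full `L_skin` when
#' `depot_drainage_mode = "full"`), and the LDC empties into the lymph node at
#' the same volumetric rate. Renal clearance `FGFR x GFR` acts on kidney
#' vascular plasma; non-renal clearance, scaled from the reference primate by
#' body weight, is apportioned over venous and arterial plasma and all
#' interstitial spaces by relative volume. Because every transfer appears once
#' as an outflux and once as an influx, all column sums of the rate matrix
#' (clearances accumulate into bookkeeping states) are zero: total mass is
#' conserved by construction, which is asserted at build time.
#'
#' @param individual One row of a `virtual_population` tibble.
#' @param drug A [drug_params()].
#' @param dose A [dose_event()]; if its `vfrac` differs from the individual's,
#'   the dose event's value wins (it defines the LDC volume actually used).
#' @param include_ldc If `FALSE`, the depot drains directly into the lymph
#'   node (the pre-LDC model variant, kept for model discrimination).
#' @param overrides Optional named list overriding `ls`, `sigma_i` or `fgfr`
#'   for this individual (used by the distribution sensitivity scenarios).
#' @return An object of class `pbpk_model`: the rate matrix, compartment
#'   volumes, state names and dosing metadata.
#' @export
build_pbpk_model <- function(individual, drug, dose, include_ldc = TRUE,
                             overrides = list()) {
  validate_drug_params(drug)
  stopifnot(inherits(dose, "dose_event"), nrow(individual) == 1)
  ls <- overrides$ls %||% drug$ls
  sigma_i <- overrides$sigma_i %||% drug$sigma_i
  fgfr <- overrides$fgfr %||% drug$fgfr
  if (sigma_i < 0 || sigma_i > 1) {
    abort("sigma_i must lie in [0, 1]", class = "lymphpbpk_config_error")
  }

  hct <- individual$hematocrit
  op <- drug$organ_params[match(ORGANS, drug$organ_params$organ), ]
  sv_eff <- stats::setNames(drug$sigma_sf * op$sigma_v, ORGANS)
  if (any(sv_eff > 1 | sv_eff < 0)) {
    abort(paste0(
      "effective vascular reflection coefficient outside [0, 1] for organ(s): ",
      paste(ORGANS[sv_eff > 1 | sv_eff < 0], collapse = ", ")
    ), class = "lymphpbpk_config_error")
  }

  sn <- state_names()
  idx <- stats::setNames(seq_along(sn), sn)
  vol <- stats::setNames(numeric(length(sn)), sn)

  vol["venous"] <- individual$venous_kg * 1000 * (1 - hct)
  vol["arterial"] <- individual$arterial_kg * 1000 * (1 - hct)
  vol["lymph_node"] <- individual$lymph_kg * 1000
  organ_vol <- stats::setNames(
    unlist(individual[paste0("mass_", ORGANS)]) * 1000, ORGANS
  )
  vol[paste0("vas_", ORGANS)] <- op$fvv * organ_vol * (1 - hct)
  vol[paste0("int_", ORGANS)] <- op$fvic * organ_vol

  v_int_skin <- vol[["int_skin"]]
  v_dep <- dose$injection_volume_ml
  if (v_dep >= v_int_skin) {
    abort("injection volume exceeds the skin interstitial volume",
          class = "lymphpbpk_config_error")
  }
  vol["skin_depot"] <- v_dep
  vol["int_skin"] <- v_int_skin - v_dep  # residual skin interstitium
  vol["ldc"] <- dose$ldc_volume_ml
  vol["cleared_renal"] <- vol["cleared_nonrenal"] <- 1  # bookkeeping only
  if (any(vol <= 0)) {
    abort(paste0("non-positive compartment volume: ",
                 paste(sn[vol <= 0], collapse = ", ")),
          class = "lymphpbpk_config_error")
  }

  qp <- stats::setNames(unlist(individual[paste0("qp_", ORGANS)]), ORGANS)
  qb <- stats::setNames(unlist(individual[paste0("qb_", ORGANS)]), ORGANS)
  lymph <- stats::setNames(
    unlist(individual[paste0("lymph_flow_", ORGANS)]), ORGANS
  )
  lymph["skin"] <- ls * qb[["skin"]]
  l_skin <- lymph[["skin"]]
  l_tot <- sum(lymph)

  q_dep <- switch(drug$depot_drainage_mode,
    proportional = l_skin * v_dep / v_int_skin,
    full = l_skin
  )

  # Total plasma flow distributed from the arterial pool; lung carries it all
  # in series plus its own lymph filtrate.
  qp_systemic <- sum(qp[setdiff(ORGANS, "lung")])
  q_vl <- qp_systemic + lymph[["lung"]]

  M <- matrix(0, length(sn), length(sn), dimnames = list(sn, sn))
  transfer <- function(from, to, flow) {
    k <- flow / vol[[from]]
    M[idx[[to]], idx[[from]]] <<- M[idx[[to]], idx[[from]]] + k
    M[idx[[from]], idx[[from]]] <<- M[idx[[from]], idx[[from]]] - k
  }

  for (org in ORGANS) {
    vas <- paste0("vas_", org)
    int <- paste0("int_", org)
    inflow <- if (org == "lung") {
      q_vl
    } else if (org == "liver") {
      qp[["liver"]] + sum(qp[PORTAL_ORGANS] - lymph[PORTAL_ORGANS])
    } else {
      qp[[org]]
    }
    target <- if (org == "lung") {
      "arterial"
    } else if (org %in% PORTAL_ORGANS) {
      "vas_liver"
    } else {
      "venous"
    }
    if (org != "lung") transfer("arterial", vas, qp[[org]])
    transfer(vas, target, inflow - lymph[[org]])
    transfer(vas, int, lymph[[org]] * (1 - sv_eff[[org]]))
    l_out <- if (org == "skin") l_skin - q_dep else lymph[[org]]
    transfer(int, "lymph_node", l_out * (1 - sigma_i))
  }
  transfer("venous", "vas_lung", q_vl)
  transfer("lymph_node", "venous", l_tot)

  if (include_ldc) {
    transfer("skin_depot", "ldc", q_dep * (1 - sigma_i))
    transfer("ldc", "lymph_node", q_dep)
  } else {
    transfer("skin_depot", "lymph_node", q_dep * (1 - sigma_i))
  }

  gfr_ml_h <- individual$gfr_ml_min * 60
  cl_renal <- fgfr * gfr_ml_h
  transfer("vas_kidney", "cleared_renal", cl_renal)

  nrcl <- drug$nrcl_primate *
    (individual$weight_kg / drug$nrcl_ref_weight)^drug$nrcl_scaling_exponent
  nrcl_comps <- c("venous", "arterial", paste0("int_", ORGANS))
  v_share <- vol[nrcl_comps] / sum(vol[nrcl_comps])
  for (cc in nrcl_comps) transfer(cc, "cleared_nonrenal", nrcl * v_share[[cc]])

  # Conservation check: every transfer was entered as a matched +/- pair.
  closure <- max(abs(colSums(M)))
  if (closure > 1e-12 * max(abs(M))) {
    abort(sprintf("rate-matrix columns do not balance (max |sum| = %.3g)",
                  closure))
  }

  structure(
    list(
      M = M, volumes = vol, states = sn,
      dose = dose, include_ldc = include_ldc,
      cl_renal_ml_h = cl_renal, nrcl_ml_h = nrcl,
      gfr_ml_min = individual$gfr_ml_min,
      q_dep_ml_h = q_dep, individual_id = individual$id %||% NA_integer_
    ),
    class = "pbpk_model"
  )
}

#' Integrate a PBPK model
#'
#' Stiff integration (lsoda with the analytic constant Jacobian) of the model
#' from an initial state with the full dose in the skin depot. The
#' mass-balance residual -- the fraction of dose not accounted for by
#' compartment amounts plus cumulative clearances -- is computed at every
#' output time and must stay below 1e-6.
#'
#' @param model A [build_pbpk_model()] object.
#' @param times Increasing output grid in hours starting at 0 (0 is prepended
#'   if absent).
#' @param atol,rtol Solver tolerances (micrograms; relative).
#' @return An object of class `pbpk_sim` holding the time grid, the amount
#'   matrix (micrograms, one column per compartment), the venous plasma
#'   concentration profile and the mass-balance residuals.
#' @export
simulate_pbpk <- function(model, times, atol = 1e-10, rtol = 1e-8) {
  stopifnot(inherits(model, "pbpk_model"), !is.unsorted(times, strictly = TRUE))
  requested <- times
  if (times[1] > 0) times <- c(0, times)
  if (times[1] < 0) abort("times must start at or after 0")

  dose_ug <- model$dose$dose_mg * 1000
  y0 <- stats::setNames(numeric(length(model$states)), model$states)
  y0["skin_depot"] <- dose_ug

  out <- deSolve::lsoda(
    y = y0, times = times,
    func = function(t, y, M) list(M %*% y),
    parms = model$M,
    jacfunc = function(t, y, M) M, jactype = "fullusr",
    atol = atol, rtol = rtol
  )
  if (attr(out, "istate")[1] < 0) {
    abort(sprintf(
      "integrator failed at t = %.4g h (reached %d of %d output times); last state: %s",
      max(out[, "time"]), nrow(out), length(times),
      paste(signif(out[nrow(out), -1], 3), collapse = ", ")
    ), class = "lymphpbpk_solver_error")
  }

  keep <- out[, "time"] %in% requested
  amounts <- out[keep, model$states, drop = FALSE]
  t_out <- out[keep, "time"]

  if (dose_ug > 0 && min(amounts) < -1e-9 * dose_ug) {
    abort("negative compartment amounts beyond solver tolerance",
          class = "lymphpbpk_solver_error")
  }
  residual <- if (dose_ug > 0) (dose_ug - rowSums(amounts)) / dose_ug else
    rep(0, length(t_out))
  if (any(abs(residual) > 1e-6)) {
    abort(sprintf("mass-balance residual %.3g exceeds 1e-6",
                  max(abs(residual))), class = "lymphpbpk_solver_error")
  }

  structure(
    list(
      times = t_out,
      amounts = amounts,
      profile = tibble(
        time = t_out,
        conc = amounts[, "venous"] / model$volumes[["venous"]]
      ),
      mass_balance_residual = residual,
      model = model
    ),
    class = "pbpk_sim"
  )
}

#' Extract the venous plasma concentration profile
#'
#' @param sim A `pbpk_sim` object.
#' @param loq Optional limit of quantitation (ug/mL); when given, a `blq`
#'   flag column marks concentrations below it.
#' @return A tibble with `time` (h) and `conc` (ug/mL), plus `blq` when `loq`
#'   is given.
#' @export
plasma_profile <- function(sim, loq = NULL) {
  stopifnot(inherits(sim, "pbpk_sim"))
  out <- sim$profile
  if (!is.null(loq)) out$blq <- out$conc < loq
  out
}

#' Tidy a PBPK simulation into long compartment amounts
#'
#' @param x A `pbpk_sim` object.
#' @param ... Unused.
#' @return A tibble with `time`, `compartment`, `amount_ug`.
#' @export
tidy.pbpk_sim <- function(x, ...) {
  as_tibble(as.data.frame(x$amounts)) |>
    mutate(time = x$times) |>
    tidyr::pivot_longer(-"time", names_to = "compartment",
                        values_to = "amount_ug")
}

#' One-line summary of a PBPK simulation
#'
#' @param x A `pbpk_sim` object.
#' @param ... Unused.
#' @return A one-row tibble: dose, Cmax and Tmax of the venous profile,
#'   cumulative cleared fractions and worst mass-balance residual.
#' @export
glance.pbpk_sim <- function(x, ...) {
  dose_ug <- x$model$dose$dose_mg * 1000
  n <- nrow(x$amounts)
  tibble(
    dose_mg = x$model$dose$dose_mg,
    cmax_ug_ml = max(x$profile$conc),
    tmax_h = x$profile$time[which.max(x$profile$conc)],
    frac_cleared_renal = x$amounts[n, "cleared_renal"] / dose_ug,
    frac_cleared_nonrenal = x$amounts[n, "cleared_nonrenal"] / dose_ug,
    max_mass_balance_residual = max(abs(x$mass_balance_residual))
  )
}

#' Plot a simulated plasma concentration profile
#'
#' @param object A `pbpk_sim` object.
#' @param log_y Plot concentration on a log10 axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pbpk_sim <- function(object, log_y = FALSE, ...) {
  p <- ggplot2::ggplot(object$profile,
                       ggplot2::aes(x = .data$time, y = .data$conc)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (h)", y = expression(
      "Plasma concentration (" * mu * "g/mL)")) +
    ggplot2::theme_bw()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Simulate venous plasma profiles for every individual in a population
#'
#' Builds and integrates one model per row of `pop` at a common dose and
#' returns the concentration matrix used by the trial emulator and the
#' sensitivity analyses.
#'
#' @param pop A `virtual_population` tibble (per-individual `vfrac` column is
#'   used to size each LDC).
#' @param drug A [drug_params()].
#' @param dose_mg,conc_mg_ml Dose and injected concentration.
#' @param times Output time grid, h.
#' @param include_ldc Passed to [build_pbpk_model()].
#' @param overrides_df Optional tibble with one row per individual and any of
#'   the columns `ls`, `sigma_i`, `fgfr` (per-individual parameter draws).
#' @param vfrac_scale Multiplier applied to every individual's `vfrac`
#'   (used by the mean-perturbation sensitivity analysis).
#' @return A matrix of concentrations, `length(times)` rows by `nrow(pop)`
#'   columns, with `times` as attribute `"times"`.
#' @export
population_profiles <- function(pop, drug, dose_mg, conc_mg_ml, times,
                                include_ldc = TRUE, overrides_df = NULL,
                                vfrac_scale = 1) {
  out <- matrix(NA_real_, length(times), nrow(pop))
  for (i in seq_len(nrow(pop))) {
    ind <- pop[i, , drop = FALSE]
    ov <- if (is.null(overrides_df)) list() else
      as.list(overrides_df[i, , drop = FALSE])
    dose <- suppressWarnings(
      dose_event(dose_mg, conc_mg_ml, vfrac = ind$vfrac * vfrac_scale)
    )
    model <- build_pbpk_model(ind, drug, dose, include_ldc = include_ldc,
                              overrides = ov)
    out[, i] <- simulate_pbpk(model, times)$profile$conc
  }
  attr(out, "times") <- times
  out
}
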