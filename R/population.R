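#' Re-center an organ mass by body height
#'
#' Allometric re-centering of a reference organ mass to an individual's
#' height: `ref_mass * (h_indiv / h_ref)^p`. Used for all compartments except
#' blood, lymph (weight-scaled) and skin (BSA-scaled).
#'
#' @param ref_mass Reference organ mass, kg.
#' @param h_indiv Individual height, cm.
#' @param h_ref Reference height, cm.
#' @param p Allometric exponent (default 3/4).
#' @return Re-centered mean mass, kg. Vectorized over its arguments.
#' @export
recenter_mass_height <- function(ref_mass, h_indiv, h_ref, p = 0.75) {
  check_positive(ref_mass = ref_mass, h_indiv = h_indiv, h_ref = h_ref)
  ref_mass * (h_indiv / h_ref)^p
}

#' Re-center a blood or lymph mass by body weight
#'
#' `ref_mass * (w_indiv / w_ref)^p`; vessel masses are assumed to grow with
#' body weight rather than height.
#'
#' @param ref_mass Reference mass, kg.
#' @param w_indiv Individual body weight, kg.
#' @param w_ref Reference body weight, kg.
#' @inheritParams recenter_mass_height
#' @return Re-centered mean mass, kg.
#' @export
recenter_mass_weight <- function(ref_mass, w_indiv, w_ref, p = 0.75) {
  check_positive(ref_mass = ref_mass, w_indiv = w_indiv, w_ref = w_ref)
  ref_mass * (w_indiv / w_ref)^p
}

#' Body surface area (Gehan-George)
#'
#' `BSA = a * W^b * H^c` with a = 0.0235, b = 0.515, c = 0.422 by default.
#'
#' @param weight Body weight, kg.
#' @param height Body height, cm.
#' @param a,b,c Model constants.
#' @return Body surface area, m^2.
#' @export
bsa <- function(weight, height, a = 0.0235, b = 0.515, c = 0.422) {
  check_positive(weight = weight, height = height)
  a * weight^b * height^c
}

#' Re-center skin mass by body surface area
#'
#' Skin scales linearly with BSA: `ref_mass * bsa_indiv / bsa_ref`.
#'
#' @param ref_mass Reference skin mass, kg.
#' @param bsa_indiv Individual BSA, m^2.
#' @param bsa_ref Reference BSA, m^2.
#' @return Re-centered mean skin mass, kg.
#' @export
recenter_mass_skin <- function(ref_mass, bsa_indiv, bsa_ref) {
  check_positive(ref_mass = ref_mass, bsa_indiv = bsa_indiv,
                 bsa_ref = bsa_ref)
  ref_mass * bsa_indiv / bsa_ref
}

check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    if (any(!is.finite(args[[nm]])) || any(args[[nm]] <= 0)) {
      abort(paste0(nm, " must be positive and finite"),
            class = "lymphpbpk_domain_error")
    }
  }
  invisible(TRUE)
}

#' Sample a compartment mass
#'
#' Draws from a normal or log-normal distribution matched to the given
#' arithmetic mean and CV. Draws are symmetrically truncated to the central
#' 95 percent of the distribution (sampling by inverse CDF on
#' U(0.025, 0.975), equivalent to rejecting and redrawing values beyond the
#' 2.5th/97.5th percentiles) and, as a second safeguard against implausibly
#' small normal draws, floored at one tenth of the mean. The log-normal
#' mu/sigma are solved so the arithmetic mean and CV match the targets.
#'
#' @param mean Target arithmetic mean (> 0), kg.
#' @param cv Coefficient of variation (fraction, >= 0); `cv = 0` returns the
#'   mean exactly.
#' @param dist `"normal"` or `"lognormal"`.
#' @param n Number of draws.
#' @param truncate Apply the central-95-percent truncation.
#' @param floor Apply the mean/10 lower bound.
#' @return Numeric vector of `n` masses. Uses the current RNG stream; seed
#'   with [set.seed()] for reproducibility.
#' @export
sample_compartment_mass <- function(mean, cv, dist, n = 1,
                                    truncate = TRUE, floor = TRUE) {
  stopifnot(all(mean > 0), all(cv >= 0))
  if (all(cv == 0)) return(rep_len(mean, n))
  u <- if (truncate) stats::runif(n, 0.025, 0.975) else stats::runif(n)
  x <- switch(dist,
    normal = stats::qnorm(u, mean = mean, sd = cv * mean),
    lognormal = {
      sigma2 <- log(1 + cv^2)
      mu <- log(mean) - sigma2 / 2
      stats::qlnorm(u, meanlog = mu, sdlog = sqrt(sigma2))
    },
    abort(paste0("unknown distribution kind: ", dist),
          class = "lymphpbpk_config_error")
  )
  if (floor) x <- pmax(x, mean / 10)
  x
}

# Re-centered mean for one compartment row given per-individual drivers.
recentered_means <- function(comp_row, spec, height, w_prov, bsa_indiv) {
  ref_mass <- comp_row$fraction_bw / 100 * spec$reference_weight
  switch(comp_row$scaling,
    height = recenter_mass_height(ref_mass, height, spec$reference_height,
                                  spec$allometric_exponent),
    weight = recenter_mass_weight(ref_mass, w_prov, spec$reference_weight,
                                  spec$allometric_exponent),
    bsa = recenter_mass_skin(
      ref_mass, bsa_indiv,
      bsa(spec$reference_weight, spec$reference_height,
          spec$bsa_a, spec$bsa_b, spec$bsa_c)
    )
  )
}

# Reference perfusion, mL blood / h / g tissue, fixed across the population.
reference_perfusion <- function(spec) {
  ref_mass_g <- spec$compartments$fraction_bw[
    match(ORGANS, spec$compartments$name)] / 100 * spec$reference_weight * 1000
  qb_ref <- spec$cardiac_output * spec$flow_fractions$flow_fraction[
    match(ORGANS, spec$flow_fractions$organ)]
  stats::setNames(qb_ref / ref_mass_g, ORGANS)
}

#' Derive blood, plasma and lymph flows for sampled individuals
#'
#' Organ blood flow is the fixed reference perfusion (reference cardiac output
#' times the organ's flow fraction, divided by the reference organ mass)
#' multiplied by the individual's sampled organ mass. Plasma flow is blood
#' flow times (1 - hematocrit); lymph flow is a fixed fraction of blood flow
#' (`lo` for every organ except skin, which uses `ls`).
#'
#' @param individuals Tibble with `mass_<organ>` columns (kg) and a
#'   `hematocrit` column.
#' @param spec A [population_spec()].
#' @param drug A [drug_params()] (supplies the lymph-flow fractions).
#' @return The input tibble with `qb_<organ>`, `qp_<organ>` (mL/h) and
#'   `lymph_flow_<organ>` (mL/h) columns filled.
#' @export
derive_flows <- function(individuals, spec, drug) {
  perf <- reference_perfusion(spec)
  for (org in ORGANS) {
    mass_col <- paste0("mass_", org)
    if (!mass_col %in% names(individuals)) {
      abort(paste0("missing organ mass column: ", mass_col),
            class = "lymphpbpk_config_error")
    }
    qb <- perf[[org]] * individuals[[mass_col]] * 1000
    lfrac <- if (org == "skin") drug$ls else drug$lo
    individuals[[paste0("qb_", org)]] <- qb
    individuals[[paste0("qp_", org)]] <- qb * (1 - individuals$hematocrit)
    individuals[[paste0("lymph_flow_", org)]] <- lfrac * qb
  }
  individuals
}

#' Derive glomerular filtration rate
#'
#' GFR is renal plasma flow times the filtration fraction, converted from
#' mL/h to mL/min.
#'
#' @param individuals Tibble with `qp_kidney` (mL/h) and
#'   `filtration_fraction` columns.
#' @return The tibble with a `gfr_ml_min` column filled.
#' @export
derive_gfr <- function(individuals) {
  individuals$gfr_ml_min <-
    individuals$qp_kidney * individuals$filtration_fraction / 60
  individuals
}

#' Generate a virtual population
#'
#' Samples adult-male virtual individuals: height from a normal distribution;
#' every compartment mass from its normal or log-normal distribution
#' re-centered allometrically to the individual (height for organs, a
#' BMI-derived provisional weight for blood and lymph, BSA for skin); body
#' weight as the sum of all compartment masses; hematocrit, filtration
#' fraction and the lymphatic drainage volume fraction (Vfrac) from their
#' distributions; blood partitioned 2/3 venous, 1/3 arterial; organ blood,
#' plasma and lymph flows from fixed reference perfusion; GFR from renal
#' plasma flow times filtration fraction. Candidates outside the body-weight
#' or GFR acceptance window are discarded and resampled until exactly `n`
#' individuals are accepted.
#'
#' @param n Number of accepted individuals to return.
#' @param spec A [population_spec()].
#' @param drug A [drug_params()] (lymph-flow fractions and the Vfrac
#'   distribution).
#' @param seed Integer seed; identical seeds reproduce the population
#'   bitwise.
#' @return A tibble of class `virtual_population`, one row per accepted
#'   individual, with all sampled and derived quantities as columns and the
#'   numbers of candidates drawn/passing each filter in attribute
#'   `acceptance`.
#' @export
generate_population <- function(n, spec = population_spec(),
                                drug = drug_params(), seed) {
  stopifnot(n >= 1)
  if (missing(seed)) abort("a seed is required for population generation")
  set.seed(seed)

  accepted <- list()
  n_acc <- 0L
  n_cand <- 0L
  n_pass_weight <- 0L
  n_pass_gfr <- 0L

  while (n_acc < n) {
    m <- max(2L * (n - n_acc), 64L)
    batch <- sample_candidates(m, spec, drug)
    ok_w <- batch$weight_kg >= spec$weight_filter[1] &
      batch$weight_kg <= spec$weight_filter[2]
    ok_g <- batch$gfr_ml_min >= spec$gfr_filter[1] &
      batch$gfr_ml_min <= spec$gfr_filter[2]
    n_cand <- n_cand + m
    n_pass_weight <- n_pass_weight + sum(ok_w)
    n_pass_gfr <- n_pass_gfr + sum(ok_g)
    keep <- batch[ok_w & ok_g, , drop = FALSE]
    if (nrow(keep)) {
      accepted[[length(accepted) + 1L]] <- keep
      n_acc <- n_acc + nrow(keep)
    }
    if (n_cand >= 1e4 && n_acc / n_cand < spec$acceptance_floor) {
      failing <- if (n_pass_weight <= n_pass_gfr) "weight_filter" else "gfr_filter"
      abort(sprintf(
        "population acceptance rate %.2g below floor %.2g; dominant failing filter: %s",
        n_acc / n_cand, spec$acceptance_floor, failing
      ), class = "lymphpbpk_acceptance_error")
    }
  }

  pop <- bind_rows(accepted)[seq_len(n), , drop = FALSE]
  pop$id <- seq_len(n)
  pop <- relocate(pop, "id")
  structure(
    pop,
    class = c("virtual_population", class(tibble())),
    acceptance = list(candidates = n_cand, accepted = n_acc,
                      pass_weight = n_pass_weight, pass_gfr = n_pass_gfr),
    seed = seed
  )
}

# One vectorized batch of candidate individuals (pre-filter).
sample_candidates <- function(m, spec, drug) {
  height <- stats::rnorm(m, spec$height_mean,
                         spec$height_cv * spec$height_mean)
  height <- pmax(height, spec$height_mean / 10)
  w_prov <- spec$reference_bmi * (height / 100)^2
  bsa_indiv <- bsa(w_prov, height, spec$bsa_a, spec$bsa_b, spec$bsa_c)

  comp <- spec$compartments
  masses <- matrix(NA_real_, m, nrow(comp),
                   dimnames = list(NULL, comp$name))
  for (k in seq_len(nrow(comp))) {
    mu <- recentered_means(comp[k, ], spec, height, w_prov, bsa_indiv)
    masses[, k] <- sample_compartment_mass(mu, comp$cv[k], comp$dist[k], n = m)
  }

  hct <- sample_compartment_mass(spec$hematocrit_mean, spec$hematocrit_cv,
                                 spec$hematocrit_dist, n = m)
  hct <- pmin(hct, 0.99)
  ff <- sample_compartment_mass(spec$ff_mean, spec$ff_cv, spec$ff_dist, n = m)
  vfrac <- sample_compartment_mass(drug$vfrac_mean, drug$vfrac_cv,
                                   drug$vfrac_dist, n = m)

  out <- tibble(
    height_cm = height,
    weight_kg = rowSums(masses),
    bsa_m2 = bsa_indiv,
    hematocrit = hct,
    filtration_fraction = ff,
    vfrac = vfrac,
    blood_kg = masses[, "blood"],
    venous_kg = masses[, "blood"] * 2 / 3,
    arterial_kg = masses[, "blood"] / 3,
    lymph_kg = masses[, "lymph"]
  )
  out$bmi_kg_m2 <- out$weight_kg / (height / 100)^2
  for (org in ORGANS) out[[paste0("mass_", org)]] <- masses[, org]
  out <- derive_flows(out, spec, drug)
  derive_gfr(out)
}

#' The reference individual
#'
#' Builds the deterministic reference male: every compartment at its reference
#' mass (so body weight is exactly the reference 71 kg and height is the
#' BMI-consistent 172 cm), hematocrit, filtration fraction and Vfrac at their
#' means, with flows and GFR derived exactly as for sampled individuals.
#'
#' @inheritParams derive_flows
#' @return A one-row `virtual_population` tibble.
#' @export
reference_individual <- function(spec = population_spec(),
                                 drug = drug_params()) {
  height <- 100 * sqrt(spec$reference_weight / spec$reference_bmi)
  comp <- spec$compartments
  masses <- stats::setNames(comp$fraction_bw / 100 * spec$reference_weight,
                            comp$name)
  out <- tibble(
    id = 1L,
    height_cm = height,
    weight_kg = sum(masses),
    bsa_m2 = bsa(spec$reference_weight, spec$reference_height,
                 spec$bsa_a, spec$bsa_b, spec$bsa_c),
    hematocrit = spec$hematocrit_mean,
    filtration_fraction = spec$ff_mean,
    vfrac = drug$vfrac_mean,
    blood_kg = masses[["blood"]],
    venous_kg = masses[["blood"]] * 2 / 3,
    arterial_kg = masses[["blood"]] / 3,
    lymph_kg = masses[["lymph"]]
  )
  out$bmi_kg_m2 <- out$weight_kg / (height / 100)^2
  for (org in ORGANS) out[[paste0("mass_", org)]] <- masses[[org]]
  out <- derive_flows(out, spec, drug)
  out <- derive_gfr(out)
  structure(out, class = c("virtual_population", class(tibble())))
}

#' Summary statistics of a virtual population
#'
#' @param object A `virtual_population` tibble.
#' @param ... Unused.
#' @return A tibble with mean, SD, CV and range of weight, height, BMI and
#'   GFR.
#' @export
summary.virtual_population <- function(object, ...) {
  vars <- c(weight_kg = "weight_kg", height_cm = "height_cm",
            bmi_kg_m2 = "bmi_kg_m2", gfr_ml_min = "gfr_ml_min")
  purrr::map_dfr(vars, function(v) {
    x <- object[[v]]
    tibble(mean = mean(x), sd = stats::sd(x), cv = stats::sd(x) / mean(x),
           min = min(x), max = max(x))
  }, .id = "variable")
}

#' Histogram panel of population anthropometry
#'
#' Weight, height, BMI and derived GFR histograms for a generated population,
#' the standard qualification view of the generator output.
#'
#' @param object A `virtual_population` tibble.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.virtual_population <- function(object, bins = 30, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[, c("weight_kg", "height_cm", "bmi_kg_m2", "gfr_ml_min")],
    dplyr::everything(),
    names_to = "variable", values_to = "value"
  )
  labels <- c(weight_kg = "Body weight (kg)", height_cm = "Height (cm)",
              bmi_kg_m2 = "BMI (kg/m²)", gfr_ml_min = "GFR (mL/min)")
  df$variable <- factor(labels[df$variable], levels = unname(labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    ggplot2::facet_wrap(~variable, scales = "free") +
    ggplot2::labs(x = NULL, y = "Individuals") +
    ggplot2::theme_bw()
}
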