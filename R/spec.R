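#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Fifteen tissue compartments of the whole-body model (blood and lymph are
# carried separately; "other" is the carcass remainder).
ORGANS <- c(
  "adipose", "brain", "bone", "heart", "kidney", "large_intestine", "liver",
  "lung", "muscle", "other", "pancreas", "skin", "small_intestine", "spleen",
  "thymus"
)

# Organs whose venous outflow passes through the liver vascular space.
PORTAL_ORGANS <- c("spleen", "pancreas", "small_intestine", "large_intestine")

#' Population specification for the virtual-population generator
#'
#' Bundles the reference anthropometry (71 kg, 172 cm, BMI 24 male), the
#' per-compartment mass distributions (mean as percent of body weight,
#' coefficient of variation, normal or log-normal), the allometric scaling
#' rules, hematocrit and renal filtration-fraction distributions, cardiac
#' output and per-organ blood-flow fractions, and the body-weight and GFR
#' acceptance filters.
#'
#' The "other" compartment mean is the remainder of reference body weight not
#' covered by the named compartments, so compartment fractions always sum to
#' exactly 100 percent. Blood and lymph scale with body weight, skin with body
#' surface area, and all remaining compartments with body height, each through
#' a 3/4-power allometric re-centering.
#'
#' @param reference_weight Reference body weight, kg.
#' @param reference_height Reference body height, cm.
#' @param reference_bmi Reference body-mass index, kg/m^2; used to convert a
#'   sampled height into the provisional weight that drives weight- and
#'   BSA-based re-centering.
#' @param allometric_exponent Exponent of the allometric re-centering
#'   (default 3/4).
#' @param bsa_a,bsa_b,bsa_c Gehan-George body-surface-area constants for
#'   `BSA = a * W^b * H^c` (W kg, H cm, BSA m^2).
#' @param height_mean,height_cv Mean (cm) and CV of the normal height
#'   distribution for adult males.
#' @param hematocrit_mean,hematocrit_cv,hematocrit_dist Hematocrit
#'   distribution; `"lognormal"` or `"normal"`.
#' @param ff_mean,ff_cv,ff_dist Renal filtration-fraction distribution.
#' @param cardiac_output Reference cardiac output, mL/h (blood).
#' @param weight_filter,gfr_filter Acceptance intervals for body weight (kg)
#'   and glomerular filtration rate (mL/min).
#' @param acceptance_floor Minimum tolerated acceptance rate of the joint
#'   filters before population generation errors out.
#' @param compartments Optional replacement tibble of compartment
#'   distributions with columns `name`, `fraction_bw` (percent of body
#'   weight; `NA` for "other" means "remainder"), `cv`, `dist`
#'   (`"normal"`/`"lognormal"`), `scaling`
#'   (`"height"`/`"weight"`/`"bsa"`).
#' @param flow_fractions Optional replacement tibble with columns `organ` and
#'   `flow_fraction` (fraction of cardiac output; `NA` for "other" means
#'   "remainder"). The lung entry is the bronchial fraction used only to scale
#'   lung lymph flow; the lung vascular space itself carries total plasma flow
#'   in series.
#'
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(reference_weight = 71,
                            reference_height = 172,
                            reference_bmi = 24,
                            allometric_exponent = 0.75,
                            bsa_a = 0.0235, bsa_b = 0.515, bsa_c = 0.422,
                            height_mean = 178, height_cv = 0.04,
                            hematocrit_mean = 0.42, hematocrit_cv = 0.02,
                            hematocrit_dist = "lognormal",
                            ff_mean = 0.20, ff_cv = 0.0294,
                            ff_dist = "lognormal",
                            cardiac_output = 5600 * 60,
                            weight_filter = c(60, 80),
                            gfr_filter = c(90, 150),
                            acceptance_floor = 1e-4,
                            compartments = NULL,
                            flow_fractions = NULL) {
  compartments <- compartments %||% default_compartments()
  flow_fractions <- flow_fractions %||% default_flow_fractions()

  # "other" rows are remainders: mass fractions close to 100 % of body
  # weight, flow fractions to 100 % of cardiac output.
  i_other <- match("other", compartments$name)
  if (is.na(compartments$fraction_bw[i_other])) {
    compartments$fraction_bw[i_other] <-
      100 - sum(compartments$fraction_bw[-i_other])
  }
  j_other <- match("other", flow_fractions$organ)
  if (is.na(flow_fractions$flow_fraction[j_other])) {
    flow_fractions$flow_fraction[j_other] <-
      1 - sum(flow_fractions$flow_fraction[-j_other])
  }

  spec <- structure(
    list(
      reference_weight = reference_weight,
      reference_height = reference_height,
      reference_bmi = reference_bmi,
      allometric_exponent = allometric_exponent,
      bsa_a = bsa_a, bsa_b = bsa_b, bsa_c = bsa_c,
      height_mean = height_mean, height_cv = height_cv,
      hematocrit_mean = hematocrit_mean, hematocrit_cv = hematocrit_cv,
      hematocrit_dist = hematocrit_dist,
      ff_mean = ff_mean, ff_cv = ff_cv, ff_dist = ff_dist,
      cardiac_output = cardiac_output,
      weight_filter = weight_filter,
      gfr_filter = gfr_filter,
      acceptance_floor = acceptance_floor,
      compartments = compartments,
      flow_fractions = flow_fractions
    ),
    class = "population_spec"
  )
  validate_population_spec(spec)
  spec
}

# Per-compartment mass distributions: mean as % of reference body weight, CV
# as a fraction, distribution kind, and the anthropometric driver used for
# allometric re-centering. Lymph variability mirrors blood (a parallel
# circulatory system); "other" is the carcass remainder.
default_compartments <- function() {
  tribble_df(
    c("name", "fraction_bw", "cv", "dist", "scaling"),
    list("adipose",          18.540, 0.43, "lognormal", "height"),
    list("brain",             1.968, 0.10, "normal",    "height"),
    list("blood",             8.005, 0.22, "lognormal", "weight"),
    list("bone",             13.952, 0.14, "normal",    "height"),
    list("heart",             0.448, 0.19, "normal",    "height"),
    list("kidney",            0.421, 0.25, "normal",    "height"),
    list("large_intestine",   1.520, 0.20, "normal",    "height"),
    list("liver",             2.707, 0.23, "normal",    "height"),
    list("lung",              1.569, 0.36, "lognormal", "height"),
    list("lymph",             0.359, 0.22, "lognormal", "weight"),
    list("muscle",           40.702, 0.16, "lognormal", "height"),
    list("other",                NA, 0.20, "normal",    "height"),
    list("pancreas",          0.136, 0.27, "normal",    "height"),
    list("skin",              4.477, 0.10, "lognormal", "bsa"),
    list("small_intestine",   1.068, 0.12, "normal",    "height"),
    list("spleen",            0.244, 0.56, "lognormal", "height"),
    list("thymus",            0.008, 0.05, "lognormal", "height")
  )
}

# Fractions of cardiac output perfusing each organ in the resting reference
# male (editable; literature-typical values). The lung fraction is the
# bronchial supply and is used only to size lung lymph flow.
default_flow_fractions <- function() {
  tribble_df(
    c("organ", "flow_fraction"),
    list("adipose",         0.0500),
    list("brain",           0.1200),
    list("bone",            0.0500),
    list("heart",           0.0400),
    list("kidney",          0.1900),
    list("large_intestine", 0.0400),
    list("liver",           0.0650),
    list("lung",            0.0250),
    list("muscle",          0.1700),
    list("other",               NA),
    list("pancreas",        0.0100),
    list("skin",            0.0500),
    list("small_intestine", 0.1000),
    list("spleen",          0.0300),
    list("thymus",          0.0015)
  )
}

# Minimal row-wise tibble constructor (keeps the tables readable without
# depending on tibble::tribble quoting rules inside the package).
tribble_df <- function(header, ...) {
  rows <- list(...)
  out <- lapply(seq_along(header), function(j) {
    vapply(rows, function(r) {
      v <- r[[j]]
      if (is.null(v)) NA else v
    }, FUN.VALUE = if (is.character(rows[[1]][[j]])) character(1) else numeric(1))
  })
  names(out) <- header
  as_tibble(out)
}

#' Validate a population specification
#'
#' Checks every structural invariant at once and reports all violations in a
#' single error: positive reference anthropometry, non-negative CVs, positive
#' mass fractions summing to 100 percent of body weight, known distribution
#' kinds and scaling rules, flow fractions summing to one, and non-empty
#' weight/GFR filter intervals.
#'
#' @param spec A [population_spec()].
#' @return `spec`, invisibly, if valid.
#' @export
validate_population_spec <- function(spec) {
  problems <- character()
  comp <- spec$compartments
  if (any(comp$cv < 0)) {
    problems <- c(problems, paste0(
      "negative CV for compartment(s): ",
      paste(comp$name[comp$cv < 0], collapse = ", ")
    ))
  }
  if (any(comp$fraction_bw <= 0)) {
    problems <- c(problems, paste0(
      "non-positive mass fraction for compartment(s): ",
      paste(comp$name[comp$fraction_bw <= 0], collapse = ", ")
    ))
  }
  if (abs(sum(comp$fraction_bw) - 100) > 1e-9) {
    problems <- c(problems, sprintf(
      "compartment mass fractions sum to %.6f %%, not 100 %%",
      sum(comp$fraction_bw)
    ))
  }
  bad_dist <- setdiff(unique(comp$dist), c("normal", "lognormal"))
  if (length(bad_dist)) {
    problems <- c(problems, paste0(
      "unknown distribution kind: ", paste(bad_dist, collapse = ", ")
    ))
  }
  bad_scaling <- setdiff(unique(comp$scaling), c("height", "weight", "bsa"))
  if (length(bad_scaling)) {
    problems <- c(problems, paste0(
      "unknown scaling rule: ", paste(bad_scaling, collapse = ", ")
    ))
  }
  missing_comp <- setdiff(c(ORGANS, "blood", "lymph"), comp$name)
  if (length(missing_comp)) {
    problems <- c(problems, paste0(
      "missing compartment(s): ", paste(missing_comp, collapse = ", ")
    ))
  }
  ff <- spec$flow_fractions
  missing_flow <- setdiff(ORGANS, ff$organ)
  if (length(missing_flow)) {
    problems <- c(problems, paste0(
      "missing blood-flow fraction for organ(s): ",
      paste(missing_flow, collapse = ", ")
    ))
  }
  if (abs(sum(ff$flow_fraction) - 1) > 1e-9) {
    problems <- c(problems, sprintf(
      "organ blood-flow fractions sum to %.6f, not 1", sum(ff$flow_fraction)
    ))
  }
  for (fld in c("reference_weight", "reference_height", "reference_bmi",
                "allometric_exponent", "cardiac_output", "height_mean")) {
    if (!is.numeric(spec[[fld]]) || length(spec[[fld]]) != 1 ||
        spec[[fld]] <= 0) {
      problems <- c(problems, paste0(fld, " must be a positive scalar"))
    }
  }
  for (fld in c("weight_filter", "gfr_filter")) {
    iv <- spec[[fld]]
    if (length(iv) != 2 || diff(iv) <= 0) {
      problems <- c(problems, paste0(fld, " must be a non-empty interval"))
    }
  }
  for (fld in c("hematocrit_dist", "ff_dist")) {
    if (!spec[[fld]] %in% c("normal", "lognormal")) {
      problems <- c(problems, paste0(fld, " must be 'normal' or 'lognormal'"))
    }
  }
  if (length(problems)) {
    abort(c("invalid population specification:", problems),
          class = "lymphpbpk_config_error")
  }
  invisible(spec)
}

#' Drug transport and clearance parameters
#'
#' Parameters of the whole-body model that belong to the drug rather than the
#' anatomy: per-organ vascular reflection coefficients and their common
#' scaling factor, the lymphatic reflection coefficient, vascular and
#' interstitial volume fractions, lymph-flow fractions of blood flow, renal
#' and non-renal clearance parameters, and the distribution of the lymphatic
#' drainage-compartment volume fraction (Vfrac).
#'
#' @param sigma_sf Scaling factor applied to every organ's vascular reflection
#'   coefficient; every effective sigma_v must stay in \[0, 1\].
#' @param sigma_i Lymphatic reflection coefficient (single value, all organs).
#' @param lo Lymph flow as a fraction of organ blood flow, all organs except
#'   skin (default 0.2 percent).
#' @param ls Skin lymph flow as a fraction of skin blood flow (default
#'   0.1 percent).
#' @param fgfr Fraction of glomerular filtration rate constituting renal
#'   clearance (default 0.1 percent).
#' @param nrcl_primate Non-renal clearance in the reference primate, mL/h.
#' @param nrcl_ref_weight Reference primate body weight, kg (3.4).
#' @param nrcl_scaling_exponent Body-weight scaling exponent for non-renal
#'   clearance (default 1: simple weight ratio).
#' @param vfrac_mean,vfrac_cv Mean and CV of the per-individual lymphatic
#'   drainage-compartment volume fraction.
#' @param vfrac_dist Distribution kind for per-individual Vfrac draws
#'   (`"normal"`, truncated and floored like organ masses, or `"lognormal"`).
#' @param depot_drainage_mode `"proportional"` (depot lymph flow is the skin
#'   lymph flow times the depot share of skin interstitial volume) or
#'   `"full"` (depot drains at the full skin lymph flow).
#' @param organ_params Optional replacement tibble with columns `organ`,
#'   `sigma_v` (base vascular reflection coefficient), `fvv` (vascular
#'   fraction of organ volume) and `fvic` (interstitial fraction).
#'
#' @return An object of class `drug_params`.
#' @export
drug_params <- function(sigma_sf = 0.95,
                        sigma_i = 0.2,
                        lo = 0.002,
                        ls = 0.001,
                        fgfr = 0.001,
                        nrcl_primate = 1.9,
                        nrcl_ref_weight = 3.4,
                        nrcl_scaling_exponent = 1,
                        vfrac_mean = 0.25,
                        vfrac_cv = 0.68,
                        vfrac_dist = "normal",
                        depot_drainage_mode = "proportional",
                        organ_params = NULL) {
  drug <- structure(
    list(
      sigma_sf = sigma_sf, sigma_i = sigma_i,
      lo = lo, ls = ls, fgfr = fgfr,
      nrcl_primate = nrcl_primate,
      nrcl_ref_weight = nrcl_ref_weight,
      nrcl_scaling_exponent = nrcl_scaling_exponent,
      vfrac_mean = vfrac_mean, vfrac_cv = vfrac_cv, vfrac_dist = vfrac_dist,
      depot_drainage_mode = depot_drainage_mode,
      organ_params = organ_params %||% default_organ_params()
    ),
    class = "drug_params"
  )
  validate_drug_params(drug)
  drug
}

# Base vascular reflection coefficients and vascular/interstitial volume
# fractions per organ (platform-typical values for a large, poorly
# extravasating solute; editable via config).
default_organ_params <- function() {
  tribble_df(
    c("organ", "sigma_v", "fvv", "fvic"),
    list("adipose",         0.95, 0.010, 0.135),
    list("brain",           0.99, 0.030, 0.180),
    list("bone",            0.85, 0.040, 0.100),
    list("heart",           0.95, 0.055, 0.160),
    list("kidney",          0.90, 0.105, 0.200),
    list("large_intestine", 0.90, 0.020, 0.090),
    list("liver",           0.85, 0.085, 0.200),
    list("lung",            0.95, 0.260, 0.190),
    list("muscle",          0.95, 0.026, 0.120),
    list("other",           0.95, 0.040, 0.150),
    list("pancreas",        0.90, 0.055, 0.120),
    list("skin",            0.95, 0.020, 0.300),
    list("small_intestine", 0.90, 0.020, 0.094),
    list("spleen",          0.85, 0.220, 0.150),
    list("thymus",          0.90, 0.055, 0.150)
  )
}

#' Validate drug parameters
#'
#' Ensures every effective vascular reflection coefficient
#' `sigma_sf * sigma_v(organ)` lies in \[0, 1\] (the error names the offending
#' organs), that the lymphatic reflection coefficient is in \[0, 1\], that the
#' lymph-flow and renal-clearance fractions lie in (0, 1), and that the organ
#' parameter table is complete.
#'
#' @param drug A [drug_params()] object.
#' @return `drug`, invisibly, if valid.
#' @export
validate_drug_params <- function(drug) {
  problems <- character()
  op <- drug$organ_params
  missing_org <- setdiff(ORGANS, op$organ)
  if (length(missing_org)) {
    problems <- c(problems, paste0(
      "missing organ parameters for: ", paste(missing_org, collapse = ", ")
    ))
  }
  eff <- drug$sigma_sf * op$sigma_v
  bad <- op$organ[eff < 0 | eff > 1]
  if (length(bad)) {
    problems <- c(problems, paste0(
      "effective vascular reflection coefficient outside [0, 1] for organ(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  if (drug$sigma_i < 0 || drug$sigma_i > 1) {
    problems <- c(problems, "sigma_i must lie in [0, 1]")
  }
  for (fld in c("lo", "ls", "fgfr")) {
    if (drug[[fld]] <= 0 || drug[[fld]] >= 1) {
      problems <- c(problems, paste0(fld, " must lie in (0, 1)"))
    }
  }
  if (any(op$fvv <= 0 | op$fvic <= 0 | op$fvv + op$fvic >= 1)) {
    problems <- c(problems,
                  "fvv and fvic must be positive with fvv + fvic < 1")
  }
  if (drug$nrcl_primate < 0) {
    problems <- c(problems, "nrcl_primate must be non-negative")
  }
  if (drug$vfrac_mean <= 0 || drug$vfrac_cv < 0) {
    problems <- c(problems, "vfrac_mean must be > 0 and vfrac_cv >= 0")
  }
  if (!drug$vfrac_dist %in% c("normal", "lognormal")) {
    problems <- c(problems, "vfrac_dist must be 'normal' or 'lognormal'")
  }
  if (!drug$depot_drainage_mode %in% c("proportional", "full")) {
    problems <- c(problems,
                  "depot_drainage_mode must be 'proportional' or 'full'")
  }
  if (length(problems)) {
    abort(c("invalid drug parameters:", problems),
          class = "lymphpbpk_config_error")
  }
  invisible(drug)
}
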