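CONFIG_SECTIONS <- c("population", "drug", "trial", "solver")

population_scalar_keys <- function() {
  setdiff(names(formals(population_spec)), c("compartments", "flow_fractions"))
}
drug_scalar_keys <- function() {
  setdiff(names(formals(drug_params)), "organ_params")
}
trial_keys <- function() names(formals(trial_design))

#' Load and validate a configuration file
#'
#' Reads a single YAML document with sections `population`, `drug`, `trial`
#' and `solver`, rejects unknown sections and unknown keys (naming each), and
#' validates every structural invariant of the population specification and
#' drug parameters. All schema violations are reported together in one error.
#'
#' @param path Path to a YAML configuration file.
#' @return A list of class `lymphpbpk_config` with elements `population`
#'   (a [population_spec()]), `drug` (a [drug_params()]), `trial`
#'   (a [trial_design()]) and `solver` (list with `atol`, `rtol`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path),
          class = "lymphpbpk_config_error")
  }
  raw <- yaml::read_yaml(path)
  problems <- character()

  unknown_sections <- setdiff(names(raw), CONFIG_SECTIONS)
  if (length(unknown_sections)) {
    problems <- c(problems, paste0(
      "unknown config section(s): ", paste(unknown_sections, collapse = ", ")
    ))
  }

  check_keys <- function(given, allowed, where) {
    extra <- setdiff(given, allowed)
    if (length(extra)) {
      problems <<- c(problems, paste0(
        "unknown key(s) in ", where, ": ", paste(extra, collapse = ", ")
      ))
    }
  }

  build_section <- function(builder, args, where) {
    tryCatch(do.call(builder, args), error = function(e) {
      problems <<- c(problems, paste0(where, ": ", conditionMessage(e)))
      NULL
    })
  }

  pop_raw <- raw$population %||% list()
  check_keys(names(pop_raw),
             c(population_scalar_keys(), "compartments", "flow_fractions"),
             "population")
  pop_args <- pop_raw[intersect(names(pop_raw), population_scalar_keys())]
  for (fld in c("weight_filter", "gfr_filter")) {
    if (!is.null(pop_args[[fld]])) pop_args[[fld]] <- unlist(pop_args[[fld]])
  }
  if (!is.null(pop_raw$compartments)) {
    pop_args$compartments <- bind_rows(lapply(pop_raw$compartments, as_tibble))
  }
  if (!is.null(pop_raw$flow_fractions)) {
    pop_args$flow_fractions <- bind_rows(lapply(pop_raw$flow_fractions,
                                                as_tibble))
  }
  population <- build_section(population_spec, pop_args, "population")

  drug_raw <- raw$drug %||% list()
  check_keys(names(drug_raw), c(drug_scalar_keys(), "organ_params"), "drug")
  required_drug <- c("sigma_sf", "sigma_i", "lo", "ls", "fgfr")
  missing_drug <- setdiff(required_drug, names(drug_raw))
  if (!is.null(raw$drug) && length(missing_drug)) {
    problems <- c(problems, paste0(
      "drug: missing required key(s): ", paste(missing_drug, collapse = ", ")
    ))
  }
  drug_args <- drug_raw[intersect(names(drug_raw), drug_scalar_keys())]
  if (!is.null(drug_raw$organ_params)) {
    drug_args$organ_params <- bind_rows(lapply(drug_raw$organ_params,
                                               as_tibble))
  }
  drug <- build_section(drug_params, drug_args, "drug")

  trial_raw <- raw$trial %||% list()
  check_keys(names(trial_raw), trial_keys(), "trial")
  trial_args <- trial_raw
  if (!is.null(trial_args$cohorts)) {
    trial_args$cohorts <- bind_rows(lapply(trial_args$cohorts, as_tibble))
  }
  if (!is.null(trial_args$sampling_times)) {
    trial_args$sampling_times <- unlist(trial_args$sampling_times)
  }
  trial <- build_section(trial_design, trial_args, "trial")

  solver_raw <- raw$solver %||% list()
  check_keys(names(solver_raw), c("atol", "rtol"), "solver")
  solver <- list(atol = solver_raw$atol %||% 1e-10,
                 rtol = solver_raw$rtol %||% 1e-8)

  if (length(problems)) {
    abort(c("invalid configuration:", problems),
          class = "lymphpbpk_config_error")
  }
  structure(
    list(population = population, drug = drug, trial = trial, solver = solver),
    class = "lymphpbpk_config"
  )
}

#' Serialize a configuration back to plain lists
#'
#' The inverse of [load_config()]: `load_config(write_config(cfg, f))` is
#' semantically identical to `cfg`.
#'
#' @param config A `lymphpbpk_config` object.
#' @return A nested list mirroring the YAML schema.
#' @export
dump_config <- function(config) {
  pop <- config$population
  drug <- config$drug
  trial <- config$trial
  list(
    population = c(
      lapply(pop[population_scalar_keys()], identity),
      list(
        compartments = purrr::transpose(as.list(pop$compartments)),
        flow_fractions = purrr::transpose(as.list(pop$flow_fractions))
      )
    ),
    drug = c(
      lapply(drug[drug_scalar_keys()], identity),
      list(organ_params = purrr::transpose(as.list(drug$organ_params)))
    ),
    trial = list(
      cohorts = purrr::transpose(as.list(trial$cohorts)),
      sampling_times = trial$sampling_times,
      loq = trial$loq,
      error_prop_cv = trial$error_prop_cv,
      error_add_sd = trial$error_add_sd
    ),
    solver = config$solver
  )
}

#' Write a configuration to YAML
#'
#' @param config A `lymphpbpk_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(dump_config(config), path, precision = 15)
  invisible(path)
}

#' The packaged default configuration
#'
#' @return A `lymphpbpk_config` built entirely from in-code defaults.
#' @export
default_config <- function() {
  structure(
    list(population = population_spec(), drug = drug_params(),
         trial = trial_design(), solver = list(atol = 1e-10, rtol = 1e-8)),
    class = "lymphpbpk_config"
  )
}

#' Reproducibility manifest for a run
#'
#' Every command-line run writes exactly one manifest recording the command,
#' a digest of the configuration actually used, the seed, the package version
#' and the output files.
#'
#' @param command Name of the command executed.
#' @param config The `lymphpbpk_config` used.
#' @param seed Seed used (or `NA` for deterministic commands).
#' @param outputs Character vector of output file paths.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(command, config, seed = NA_integer_,
                         outputs = character()) {
  structure(
    list(
      command = command,
      config_digest = rlang::hash(dump_config(config)),
      seed = seed,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      package_version = as.character(utils::packageVersion("lymphpbpk")),
      outputs = outputs
    ),
    class = "run_manifest"
  )
}

#' Write a run manifest as JSON
#'
#' @param manifest A [run_manifest()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
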